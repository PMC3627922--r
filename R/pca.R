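#' Standardized PCA of the environmental layer stack
#'
#' Each appellation is characterized by principal components analysis of
#' seven environmental surfaces: elevation, soil AWC, soil pH, depth to
#' restrictive layer, GDD, FFD, and growing-season precipitation.
#' (Slope, aspect, and insolation are DEM-derived and would duplicate
#' elevation's signal; drainage is categorical; BEDD shares its source
#' with GDD -- all are excluded.) Layers are standardized to z-scores
#' over the common validity mask, so the decomposed covariance matrix is
#' the correlation matrix of the raw layers.
#'
#' @name pca_stack
NULL

#' Layer order of the PCA stack
#' @export
STACK_LAYERS <- c("elevation", "awc", "ph", "depth", "gdd", "ffd", "gsp")

#' Build a PCA layer stack
#'
#' Assembles the seven co-registered layers and their common validity
#' mask (cells with data in every layer).
#'
#' @param layers named list of `grid`s containing at least the
#'   [STACK_LAYERS] names.
#' @return object of class `stack_spec`: list with `layers` (in stack
#'   order), `mask` (logical matrix of jointly valid cells), and
#'   `standardized` flag.
#' @export
stack_spec <- function(layers) {
  miss <- setdiff(STACK_LAYERS, names(layers))
  if (length(miss))
    stop(sprintf("missing stack layer(s): %s", paste(miss, collapse = ", ")))
  layers <- layers[STACK_LAYERS]
  ref <- layers[[1]]
  mask <- !is.na(ref$values)
  for (nm in STACK_LAYERS[-1]) {
    check_aligned(ref, layers[[nm]], sprintf("stack layer '%s'", nm))
    mask <- mask & !is.na(layers[[nm]]$values)
  }
  structure(list(layers = layers, mask = mask, standardized = FALSE),
            class = "stack_spec")
}

# Stack values over the mask as an n x 7 matrix.
stack_matrix <- function(stack) {
  vapply(stack$layers, function(g) g$values[stack$mask],
         numeric(sum(stack$mask)))
}

#' Standardize stack layers to z-scores
#'
#' Subtracts each layer's mean and divides by its standard deviation,
#' computed over the common mask. The population (1/n) denominator is
#' the default; `sd = "sample"` selects 1/(n-1). At raster cell counts
#' the difference is negligible, but the choice is pinned for exact
#' reproducibility. A constant layer has no z-score and is rejected by
#' name.
#'
#' @param stack a [stack_spec()].
#' @param sd `"population"` or `"sample"`.
#' @return the standardized `stack_spec` (means 0, SDs 1 on the mask).
#' @export
standardize_layers <- function(stack, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(inherits(stack, "stack_spec"))
  n <- sum(stack$mask)
  if (n < 2) stop("fewer than 2 cells in the stack mask")
  for (nm in names(stack$layers)) {
    g <- stack$layers[[nm]]
    vals <- g$values[stack$mask]
    mu <- mean(vals)
    ss <- sum((vals - mu)^2)
    denom <- if (sd == "population") n else n - 1
    s <- sqrt(ss / denom)
    if (s == 0) stop(sprintf("layer '%s' is constant (zero variance)", nm))
    v <- (g$values - mu) / s
    v[!stack$mask] <- NA
    stack$layers[[nm]] <- grid_like(g, v)
  }
  stack$standardized <- TRUE
  stack$sd_kind <- sd
  stack
}

#' Principal components of the standardized stack
#'
#' Eigen-decomposition of the 7 x 7 covariance matrix of the
#' standardized layers over the mask (the correlation matrix of the raw
#' layers). Loadings are sign-fixed so each eigenvector's
#' largest-magnitude component is positive, making the result unique.
#'
#' @param stack a standardized [stack_spec()] (see
#'   [standardize_layers()]; an unstandardized stack is standardized
#'   on the fly with the population SD).
#' @param k number of components to retain (default all 7).
#' @return object of class `pca_result`: `eigenvalues` (descending),
#'   `variance_fractions`, `cumulative_fractions`, `loadings` (7 x k,
#'   rownames = layer names), `correlation` (the decomposed matrix),
#'   and `n` (mask cell count).
#' @export
principal_components <- function(stack, k = length(STACK_LAYERS)) {
  stopifnot(inherits(stack, "stack_spec"))
  p <- length(stack$layers)
  if (k < 1 || k > p) stop("k must be between 1 and the layer count")
  n <- sum(stack$mask)
  if (n < p) stop("fewer mask cells than layers")
  if (!isTRUE(stack$standardized)) stack <- standardize_layers(stack)
  Z <- stack_matrix(stack)
  denom <- if (identical(stack$sd_kind, "sample")) n - 1 else n
  C <- crossprod(Z) / denom
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- names(stack$layers)
  ev <- eig$values
  vf <- ev / sum(ev)
  structure(list(eigenvalues = ev,
                 variance_fractions = vf,
                 cumulative_fractions = cumsum(vf),
                 loadings = V[, seq_len(k), drop = FALSE],
                 correlation = C,
                 n = n),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d layers, n = %d cells\n",
              nrow(x$loadings), x$n))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fractions), collapse = " "), "\n")
  invisible(x)
}

#' Cumulative variance explained by the first j components
#'
#' @param result a [principal_components()] result.
#' @param j number of leading components.
#' @return fraction of total variance in \[0, 1\].
#' @export
cumulative_variance <- function(result, j) {
  stopifnot(inherits(result, "pca_result"))
  if (j < 1 || j > length(result$variance_fractions))
    stop("j out of range")
  result$cumulative_fractions[[j]]
}
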