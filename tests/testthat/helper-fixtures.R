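# Shared fixtures, built once per test run. Kept small (grid 32/64) so the
# whole suite stays fast; individual tests that need other conditions build
# their own subjects.

fixture_env <- new.env()

fx_atlas64 <- function() {
  if (is.null(fixture_env$at64))
    fixture_env$at64 <- make_atlas(64, seed = 1)
  fixture_env$at64
}

fx_atlas32 <- function() {
  if (is.null(fixture_env$at32))
    fixture_env$at32 <- make_atlas(32, seed = 1)
  fixture_env$at32
}

# A random valid parcellation/mask pair on a small grid, for oracle tests.
random_label_volume <- function(n = 16, seed = 1) {
  set.seed(seed)
  label_volume(array(sample(0:35, n^3, replace = TRUE), c(n, n, n)))
}

random_mask <- function(n = 16, seed = 1, p = 0.3) {
  set.seed(seed)
  binary_mask(array(rbinom(n^3, 1, p), c(n, n, n)))
}

# Synthetic 43-column feature table with given labels; bd columns are noise
# unless overridden. Used by classifier tests that do not need the imaging
# pipeline.
synthetic_feature_table <- function(n, categories, seed = 1) {
  set.seed(seed)
  X <- matrix(abs(rnorm(n * 43, sd = 0.05)), n, 43)
  colnames(X) <- hemomap:::feature_colnames()
  tab <- cbind(data.frame(id = sprintf("T%03d", seq_len(n))),
               as.data.frame(X, check.names = FALSE))
  tab$sap_category <- categories
  class(tab) <- c("sap_feature_table", "data.frame")
  tab
}

# Brute-force reference implementation of binned mutual information:
# explicit double loop over all histogram cells.
mi_bruteforce <- function(x, y, bins) {
  rx <- range(x); ry <- range(y)
  bx <- pmin(floor((x - rx[1]) / (rx[2] - rx[1]) * bins), bins - 1) + 1
  by <- pmin(floor((y - ry[1]) / (ry[2] - ry[1]) * bins), bins - 1) + 1
  h <- matrix(0, bins, bins)
  for (t in seq_along(bx)) h[bx[t], by[t]] <- h[bx[t], by[t]] + 1
  p <- h / sum(h)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in 1:bins) for (j in 1:bins)
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  mi
}

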