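# Internal helpers shared across modules.

# vacuum speed of light in mm/ps (ps <-> THz makes this the natural unit system)
C_MM_PER_PS <- 0.299792458

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "thzash_invalid_config", ...)
}

abort_nonfinite <- function(msg, report) {
  rlang::abort(msg, class = "thzash_nonfinite", report = report)
}

#' Unwrap a phase vector
#'
#' Removes 2*pi jumps between adjacent points, anchoring at the first element.
#' @param phi numeric vector of phases in radians, ordered by frequency.
#' @return numeric vector of the same length with no adjacent step exceeding pi.
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1] + c(0, cumsum(d))
}

# centered running mean with shrinking windows at the edges
running_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1 || n < 2) return(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# logical mask of the longest contiguous TRUE run (first run wins ties)
longest_true_run <- function(x) {
  r <- rle(x)
  out <- rep(FALSE, length(x))
  if (!any(r$values)) return(out)
  lens <- ifelse(r$values, r$lengths, 0L)
  k <- which.max(lens)
  start <- sum(r$lengths[seq_len(k - 1)]) + 1L
  out[start:(start + r$lengths[k] - 1L)] <- TRUE
  out
}

# Counter-based stream derivation from one master seed so that per-sample /
# per-replicate random draws do not depend on iteration order. Stays inside
# 32-bit integer range (and exact double arithmetic, < 2^53).
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (i in c(...)) {
    s <- (s * 48271 + (as.numeric(i) + 1) * 2654435.0) %% 2147483647
  }
  as.integer(s)
}

# coerce a data frame / matrix of spectra to a plain numeric matrix
as_spectral_matrix <- function(X) {
  if (is.data.frame(X)) {
    num <- vapply(X, is.numeric, logical(1))
    X <- as.matrix(X[, num, drop = FALSE])
  }
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  storage.mode(X) <- "double"
  X
}

check_finite_or_abort <- function(X, context) {
  rep <- assert_finite(X)
  if (nrow(rep) > 0) {
    abort_nonfinite(
      sprintf("%s: input matrix contains %d non-finite entries; refusing to fit (see the attached report).",
              context, nrow(rep)),
      report = rep
    )
  }
  invisible(TRUE)
}
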