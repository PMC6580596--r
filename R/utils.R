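#' @useDynLib pancanrx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pt pf pnorm sd var rnorm runif kmeans predict
#'   complete.cases quantile p.adjust wilcox.test setNames median
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG
#' state, so seeded package functions never disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Deterministic across platforms and execution order: a small polynomial
#' string hash folded with the master seed, kept inside the 32-bit
#' integer range R requires of `set.seed`.
#'
#' @param master integer master seed.
#' @param ... character/numeric labels identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                         character(1)), collapse = "::")
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stop_pancanrx <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "pancanrx_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Column-wise Spearman correlation with t-approximation p-values
#'
#' Correlates every column of `X` with `y` using Spearman's rank
#' correlation; p-values come from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df. Constant
#' columns get `rho = NA`, `p = 1` (they carry no ordering information).
#'
#' @param X numeric matrix (observations x variables).
#' @param y numeric vector, `length(y) == nrow(X)`.
#' @return data.frame with columns `rho` and `p`, one row per column of `X`.
#' @keywords internal
spearman_screen_stats <- function(X, y) {
  n <- nrow(X)
  if (n < 5L) stop_pancanrx("need at least 5 observations for the Spearman screen",
                            "pancanrx_too_few_cells")
  if (sd(y) == 0) stop_pancanrx("response is constant; Spearman screen undefined",
                                "pancanrx_constant_response")
  ry <- rank(y)
  rX <- apply(X, 2L, rank)
  sds <- apply(rX, 2L, sd)
  const <- sds == 0
  rho <- rep(NA_real_, ncol(X))
  if (any(!const)) {
    rho[!const] <- as.vector(cor(rX[, !const, drop = FALSE], ry))
  }
  p <- spearman_p(rho, n)
  p[const] <- 1
  data.frame(rho = rho, p = p, row.names = colnames(X))
}

# two-sided p for Spearman rho via the Student-t approximation
spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 2)
}

# Spearman rho of two vectors (Pearson on ranks); NA if either is constant
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}
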