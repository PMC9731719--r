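# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package operations never perturb user code.
#'
#' @param seed integer scalar seed (NULL leaves the RNG untouched).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit child seed from (seed, index) without consuming
# the caller's stream; keeps every internal source of randomness tied to one
# user-visible seed.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7907 * as.double(index)) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_input("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a finite number", name)
  }
  if (strict_lower && x <= lower) stop_input("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower) stop_input("`%s` must be >= %g", name, lower)
  if (strict_upper && x >= upper) stop_input("`%s` must be < %g", name, upper)
  if (!strict_upper && x > upper) stop_input("`%s` must be <= %g", name, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 0) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_input("`%s` must be a whole number", name)
  invisible(as.integer(x))
}

# Reflect-pad a vector by r elements on each side (edge value repeated, as in
# scipy's "reflect" mode): c(b, a, | a, b, c, | c, b).
reflect_pad <- function(x, r) {
  n <- length(x)
  if (r == 0L) return(x)
  left <- x[pmin(r:1, n)]
  right <- x[pmax(n - (1:r) + 1L, 1L)]
  c(left, x, right)
}

# Sliding-window extreme over windows of length w (fully inside x), using the
# van Herk / Gil-Werman block decomposition; vectorised, O(n).
slide_extreme <- function(x, w, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(x)
  if (w == 1L) return(x)
  pad_val <- if (op == "min") Inf else -Inf
  nb <- ceiling(n / w)
  xp <- c(x, rep(pad_val, nb * w - n))
  m <- matrix(xp, nrow = w)
  pfun <- if (op == "min") pmin else pmax
  pref <- m                                        # block-prefix extremes
  for (i in seq_len(w)[-1L]) pref[i, ] <- pfun(pref[i, ], pref[i - 1L, ])
  suff <- m                                        # block-suffix extremes
  for (i in rev(seq_len(w - 1L))) suff[i, ] <- pfun(suff[i, ], suff[i + 1L, ])
  pref <- as.vector(pref)
  suff <- as.vector(suff)
  i <- seq_len(n - w + 1L)
  out <- if (op == "min") pmin(suff[i], pref[i + w - 1L]) else
    pmax(suff[i], pref[i + w - 1L])
  out
}

# Centered running min/max with window half-width r and reflect boundary.
running_extreme <- function(x, r, op) {
  if (r == 0L) return(x)
  slide_extreme(reflect_pad(x, r), 2L * r + 1L, op)
}

# Stratified assignment of indices to k folds, seeded; returns integer fold id
# per observation.
stratified_folds <- function(y, k, seed = NULL) {
  y <- as.integer(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop_input("class %s has %d subjects, fewer than %d folds",
                   cls, length(idx), k)
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}
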