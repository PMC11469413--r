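#' Construct a circuit parameter set
#'
#' Bundles all constants of the two-population divisive-normalization
#' circuit: `n` principal neurons `y` whose recurrent drive is gated by `n`
#' modulator neurons `a`. Scalars are broadcast to length-`n` vectors, and
#' `W_r` / `W` default to the identity and the all-ones normalization pool.
#'
#' @param n Number of principal neurons (the modulator population has the
#'   same size).
#' @param tau_y,tau_a Membrane time constants (ms), strictly positive;
#'   scalar or length-`n`.
#' @param b Input gains for the principal neurons, strictly positive.
#' @param b0 Input gains of the modulator neurons, strictly positive.
#' @param sigma Semisaturation constants, strictly positive. Together with
#'   `b0` they set the floor of the normalization denominator.
#' @param W_r `n x n` recurrent weight matrix between principal neurons
#'   (scalar allowed when `n = 1`).
#' @param W `n x n` nonnegative normalization-pool weight matrix: entry
#'   `W[i, j]` is the weight with which neuron `j`'s activity divides
#'   neuron `i`'s response.
#' @param W_zx Optional `n x m` input-encoding matrix mapping an external
#'   input `x` to the input drive `z = W_zx x`. When `NULL` the input is
#'   passed through unchanged (`m = n`).
#'
#' @return An object of class `organics_params` (a validated list).
#' @export
#' @examples
#' p <- organics_params(n = 2, b = 0.5, b0 = 0.5, sigma = 0.1)
#' p$sigma
organics_params <- function(n,
                            tau_y = 2,
                            tau_a = 2,
                            b = 1,
                            b0 = 1,
                            sigma = 1,
                            W_r = diag(n),
                            W = matrix(1, n, n),
                            W_zx = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  n <- as.integer(n)
  bc <- function(v, nm) {
    if (length(v) == 1) v <- rep(as.numeric(v), n)
    if (length(v) != n) {
      stop(sprintf("`%s` must be a scalar or length-%d vector", nm, n))
    }
    as.numeric(v)
  }
  as_mat <- function(m, nm) {
    if (length(m) == 1 && n == 1) m <- matrix(as.numeric(m), 1, 1)
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, n))) stop(sprintf("`%s` must be %d x %d", nm, n, n))
    storage.mode(m) <- "double"
    m
  }
  p <- structure(
    list(
      n = n,
      tau_y = bc(tau_y, "tau_y"), tau_a = bc(tau_a, "tau_a"),
      b = bc(b, "b"), b0 = bc(b0, "b0"), sigma = bc(sigma, "sigma"),
      W_r = as_mat(W_r, "W_r"), W = as_mat(W, "W"),
      W_zx = if (!is.null(W_zx)) {
        W_zx <- as.matrix(W_zx)
        storage.mode(W_zx) <- "double"
        if (nrow(W_zx) != n) stop("`W_zx` must have n rows")
        W_zx
      }
    ),
    class = "organics_params"
  )
  validate_params(p)
}

#' Validate a circuit parameter set
#'
#' Checks positivity of the time constants, gains and semisaturation,
#' nonnegativity of the normalization weights, and dimensional coherence.
#' Called by [organics_params()]; useful directly after manual edits.
#'
#' @param p An `organics_params` object.
#' @return `p`, invisibly unchanged, or an error.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "organics_params"))
  n <- p$n
  for (nm in c("tau_y", "tau_a", "b", "b0", "sigma")) {
    v <- p[[nm]]
    if (length(v) != n || !all(is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be a strictly positive, finite length-%d vector", nm, n))
    }
  }
  if (!all(dim(p$W) == c(n, n)) || any(p$W < 0) || !all(is.finite(p$W))) {
    stop("`W` must be a nonnegative finite n x n matrix")
  }
  if (!all(dim(p$W_r) == c(n, n)) || !all(is.finite(p$W_r))) {
    stop("`W_r` must be a finite n x n matrix")
  }
  invisible(p)
}

#' @export
print.organics_params <- function(x, ...) {
  cat(sprintf("<organics_params> n = %d\n", x$n))
  fmt <- function(v) {
    if (length(unique(v)) == 1) format(v[1]) else paste0("[", paste(signif(v, 4), collapse = ", "), "]")
  }
  cat(sprintf("  tau_y = %s ms, tau_a = %s ms\n", fmt(x$tau_y), fmt(x$tau_a)))
  cat(sprintf("  b = %s, b0 = %s, sigma = %s\n", fmt(x$b), fmt(x$b0), fmt(x$sigma)))
  id <- identical(dim(x$W_r), c(x$n, x$n)) &&
    max(abs(x$W_r - diag(x$n))) < 1e-12
  cat(sprintf("  W_r: %s, W: max %.3g, W_zx: %s\n",
              if (id) "identity" else sprintf("sigma_max %.3g", max(svd(x$W_r)$d)),
              max(x$W), if (is.null(x$W_zx)) "pass-through" else
                paste(dim(x$W_zx), collapse = " x ")))
  invisible(x)
}

#' Read / write a circuit parameter set as JSON
#'
#' The on-disk format stores each field by name; scalar entries broadcast
#' to length-`n` on read, matrices are nested arrays. All command-line
#' subcommands share this format.
#'
#' @param path File path.
#' @param p An `organics_params` object.
#' @return `read_params_json()` returns an `organics_params`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$n)) stop("config must contain `n`")
  as_mat <- function(x, nr) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = nr, byrow = TRUE)
  }
  organics_params(
    n = j$n,
    tau_y = j$tau_y %||% 2, tau_a = j$tau_a %||% 2,
    b = j$b %||% 1, b0 = j$b0 %||% 1, sigma = j$sigma %||% 1,
    W_r = if (!is.null(j$W_r)) as_mat(j$W_r, j$n) else diag(j$n),
    W = if (!is.null(j$W)) as_mat(j$W, j$n) else matrix(1, j$n, j$n),
    W_zx = if (!is.null(j$W_zx)) as_mat(j$W_zx, j$n)
  )
}

#' @rdname read_params_json
#' @export
write_params_json <- function(p, path) {
  validate_params(p)
  x <- list(
    n = p$n, tau_y = p$tau_y, tau_a = p$tau_a,
    b = p$b, b0 = p$b0, sigma = p$sigma,
    W_r = apply(p$W_r, 1, identity, simplify = FALSE),
    W = apply(p$W, 1, identity, simplify = FALSE)
  )
  if (!is.null(p$W_zx)) x$W_zx <- apply(p$W_zx, 1, identity, simplify = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE when W_r is the identity to within `tol`
has_identity_recurrence <- function(p, tol = 1e-10) {
  max(abs(p$W_r - diag(p$n))) <= tol
}
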