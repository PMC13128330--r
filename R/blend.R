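#' Blending parameters
#'
#' The blended similarity is
#' `S_blend = c0 * W + sum_i ci * (W^pw (x) Si^psi)` with element-wise
#' powers and products. The coefficients form a simplex (`ci >= 0`,
#' `sum ci = 1`) and all exponents are box-bounded to `[0, 4]`, a range
#' broad enough for strong non-linear sharpening (exponent > 1 makes
#' high similarities more distinct) or softening (exponent < 1).
#'
#' @param c numeric vector of `k + 1` simplex coefficients
#'   `(c0, c1, ..., ck)`.
#' @param pw shared exponent applied to `W` inside the interaction terms.
#' @param ps numeric vector of `k` per-view exponents.
#' @return an object of class `blend_params`.
#' @export
blend_params <- function(c, pw, ps) {
  p <- structure(list(c = as.numeric(c), pw = as.numeric(pw),
                      ps = as.numeric(ps)),
                 class = "blend_params")
  validate_blend_params(p)
  p
}

validate_blend_params <- function(p, k = length(p$ps)) {
  if (length(p$c) != k + 1L) {
    stop("expected ", k + 1L, " coefficients, got ", length(p$c))
  }
  if (any(p$c < -1e-9)) {
    stop("coefficient constraint violated: ci >= 0 (got min ", min(p$c), ")")
  }
  if (abs(sum(p$c) - 1) > 1e-9) {
    stop("coefficient constraint violated: sum(ci) = 1 (got ", sum(p$c), ")")
  }
  if (length(p$pw) != 1L || p$pw < 0 || p$pw > 4) {
    stop("exponent constraint violated: 0 <= pw <= 4 (got ", p$pw, ")")
  }
  if (length(p$ps) != k || any(p$ps < 0) || any(p$ps > 4)) {
    stop("exponent constraint violated: 0 <= ps_i <= 4")
  }
  invisible(p)
}

#' @export
print.blend_params <- function(x, ...) {
  cat("blend_params: c0 =", signif(x$c[1], 4),
      " c =", paste(signif(x$c[-1], 4), collapse = " "),
      " pw =", signif(x$pw, 4),
      " ps =", paste(signif(x$ps, 4), collapse = " "), "\n")
  invisible(x)
}

#' The identity configuration
#'
#' `c0 = 1`, all view coefficients zero: the blend reduces to `W`
#' exactly, so the full pipeline reproduces plain average linkage. It is
#' the baseline configuration seeded into every optimizer run.
#'
#' @param k number of views.
#' @return a [blend_params()].
#' @export
identity_params <- function(k) {
  blend_params(c = c(1, rep(0, k)), pw = 1, ps = rep(1, k))
}

#' Blend a similarity matrix with its views
#'
#' Element-wise model `S_blend = c0 W + sum_i ci (W^pw (x) Si^psi)`.
#' The interaction term re-weights each view by the original matrix:
#' when both agree a pair is similar the product amplifies the signal,
#' when either disagrees it is suppressed. `0^0` is defined as 1, so a
#' zero exponent cleanly deletes a factor (e.g. `pw = 0` removes the
#' W-gating). The diagonal stays zero and symmetry is preserved.
#'
#' @param W similarity matrix.
#' @param views named list of view similarity matrices (see
#'   [build_view_set()]).
#' @param params a [blend_params()] with `k = length(views)`.
#' @return the blended similarity matrix.
#' @export
blend <- function(W, views, params) {
  W <- as_similarity(W)
  if (length(views) < 1L) stop("need at least one view")
  validate_blend_params(params, k = length(views))
  Wp <- W^params$pw  # R defines 0^0 = 1, as required here
  S <- params$c[1] * W
  for (i in seq_along(views)) {
    V <- align_similarity(as_similarity(views[[i]]), rownames(W))
    S <- S + params$c[i + 1L] * (Wp * V^params$ps[i])
  }
  diag(S) <- 0
  as_similarity(S, ids = rownames(W))
}

#' Project a raw parameter vector onto the feasible set
#'
#' Maps an unconstrained optimizer proposal of length `2k + 2`
#' (`c0..ck, pw, ps1..psk`) onto the constraint set: coefficients are
#' clipped at zero and renormalized to sum one (an all-zero vector
#' falls back to uniform), exponents are clipped to `[0, 4]`.
#' Clip-and-renormalize (rather than softmax) preserves exact zeros,
#' which the optimizer uses to switch views off entirely.
#'
#' @param raw numeric vector of length `2k + 2`.
#' @param k number of views.
#' @return a [blend_params()].
#' @export
project_params <- function(raw, k) {
  if (length(raw) != 2 * k + 2) {
    stop("raw parameter vector must have length ", 2 * k + 2,
         ", got ", length(raw))
  }
  cs <- pmax(raw[seq_len(k + 1)], 0)
  cs <- if (sum(cs) <= 0) rep(1 / (k + 1), k + 1) else cs / sum(cs)
  pw <- min(max(raw[k + 2], 0), 4)
  ps <- pmin(pmax(raw[seq.int(k + 3, 2 * k + 2)], 0), 4)
  blend_params(cs, pw, ps)
}

params_to_vector <- function(p) c(p$c, p$pw, p$ps)

vector_to_params <- function(v, k) {
  blend_params(v[seq_len(k + 1)], v[k + 2], v[seq.int(k + 3, 2 * k + 2)])
}

#' Serialize / deserialize blending parameters as JSON
#'
#' Flat object `{"c": [...], "pw": ..., "ps": [...]}`, used in result
#' bundles and for the learned-parameter introspection report.
#'
#' @param params a [blend_params()].
#' @param path file path.
#' @return `read_blend_params` returns a [blend_params()].
#' @export
write_blend_params <- function(params, path) {
  jsonlite::write_json(list(c = params$c, pw = params$pw, ps = params$ps),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blend_params
#' @export
read_blend_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  blend_params(x$c, x$pw, x$ps)
}
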