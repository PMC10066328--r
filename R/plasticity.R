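# The pool of ten candidate plasticity terms and their linear combination.

#' Local signals available to one weight matrix
#'
#' Bundles the quantities a local plasticity rule may read when updating the
#' layer-l weight matrix `W_{l-1,l}`: the pre-synaptic activation `y_{l-1}`,
#' post-synaptic activation `y_l`, pre-synaptic error `e_{l-1}` (the
#' synthetic `e_0` for the first layer), post-synaptic error `e_l`, and the
#' current weight matrix itself.
#'
#' @param y_pre,y_post activation vectors (lengths n_pre, n_post).
#' @param e_pre,e_post error vectors (lengths n_pre, n_post).
#' @param W current weight matrix, shape n_post x n_pre.
#' @return an object of class `local_signals`.
#' @export
local_signals <- function(y_pre, y_post, e_pre, e_post, W) {
  y_pre <- as.vector(y_pre); y_post <- as.vector(y_post)
  e_pre <- as.vector(e_pre); e_post <- as.vector(e_post)
  if (!is.matrix(W)) stop("W must be a matrix")
  if (length(y_pre) != ncol(W) || length(e_pre) != ncol(W))
    stop("pre-synaptic signal length must equal ncol(W)")
  if (length(y_post) != nrow(W) || length(e_post) != nrow(W))
    stop("post-synaptic signal length must equal nrow(W)")
  structure(list(y_pre = y_pre, y_post = y_post,
                 e_pre = e_pre, e_post = e_post, W = W),
            class = "local_signals")
}

# outer product closed under complex arithmetic
.outer_c <- function(a, b) a %o% b

#' Evaluate one candidate plasticity term
#'
#' The ten terms, indexed r = 0..9, are quadratic (or lower-order) local
#' combinations of the signals in [local_signals()]; each returns a matrix
#' of the same shape as `W`. Writing `y, e` for activations/errors and
#' post/pre subscripts implicitly:
#' \describe{
#'   \item{F0}{`-e_post y_pre^T`, the (pseudo-)gradient term}
#'   \item{F1}{`-y_post e_pre^T`}
#'   \item{F2}{`-e_post e_pre^T`, the error-Hebbian (eHebb) term}
#'   \item{F3}{`-W`, weight decay}
#'   \item{F4}{`-1 e_pre^T` (ones of the post-synaptic dimension)}
#'   \item{F5}{`-e_post (1^T y_post) y_pre^T`}
#'   \item{F6}{`-y_post y_post^T W e_pre e_pre^T`}
#'   \item{F7}{`-e_post y_post^T W e_pre y_pre^T`}
#'   \item{F8}{`-y_post y_pre^T W^T e_post e_pre^T`}
#'   \item{F9}{`y_post y_pre^T - (y_post y_post^T) W`, Oja's rule applied to
#'     post-nonlinearity activations (Hebbian growth with an orthonormalizing
#'     stabilizer)}
#' }
#'
#' @param r term index in 0..9.
#' @param s a [local_signals()] bundle.
#' @return matrix of the same shape as `s$W`.
#' @export
plasticity_term <- function(r, s) {
  if (!is.numeric(r) || length(r) != 1 || !(r %in% 0:9))
    stop("term index r must be a single integer in 0..9")
  yp <- s$y_pre; yq <- s$y_post; ep <- s$e_pre; eq <- s$e_post; W <- s$W
  switch(as.character(r),
    "0" = -.outer_c(eq, yp),
    "1" = -.outer_c(yq, ep),
    "2" = -.outer_c(eq, ep),
    "3" = -W,
    "4" = -.outer_c(rep(1, length(yq)), ep),
    "5" = -sum(yq) * .outer_c(eq, yp),
    # F6..F8 contract to a scalar times an outer product:
    "6" = -as.vector(yq %*% W %*% ep)[1] * .outer_c(yq, ep),
    "7" = -as.vector(yq %*% W %*% ep)[1] * .outer_c(eq, yp),
    "8" = -as.vector(eq %*% W %*% yp)[1] * .outer_c(yq, ep),
    "9" = .outer_c(yq, yp) - .outer_c(yq, as.vector(t(W) %*% yq))
  )
}

#' Plasticity rule: active terms and shared coefficients
#'
#' A rule is a coefficient vector `theta` of length 10 (one entry per
#' candidate term) together with the set of active term indices; inactive
#' coefficients are identically zero. Under meta-parameter sharing one rule
#' object governs every layer of the network.
#'
#' @param active_terms integer vector of term indices (0-based, subset of
#'   0..9) included in the rule.
#' @param theta_init named or positional numeric vector of initial
#'   coefficients for the active terms, recycled/defaulted to 0; or a full
#'   length-10 vector.
#' @return an object of class `plasticity_rule` with fields `theta`
#'   (length 10, names `theta_0 ... theta_9`) and `active`.
#' @export
plasticity_rule <- function(active_terms, theta_init = NULL) {
  active_terms <- sort(unique(as.integer(active_terms)))
  if (length(active_terms) == 0 || any(!(active_terms %in% 0:9)))
    stop("active_terms must be a non-empty subset of 0..9")
  theta <- stats::setNames(numeric(10), paste0("theta_", 0:9))
  if (!is.null(theta_init)) {
    if (length(theta_init) == 10) {
      theta[] <- theta_init
    } else {
      if (length(theta_init) != length(active_terms))
        stop("theta_init must match active_terms (or have length 10)")
      theta[active_terms + 1] <- theta_init
    }
  }
  if (any(theta[setdiff(0:9, active_terms) + 1] != 0))
    stop("coefficients of inactive terms must be zero")
  structure(list(theta = theta, active = active_terms),
            class = "plasticity_rule")
}

#' Named composite rules
#'
#' Presets for the rules studied with this framework. All start from a
#' learning rate `theta_0 = 1e-3` with every other coefficient zero:
#' \describe{
#'   \item{FA_baseline}{term 0 only (pseudo-gradient with a learned rate).}
#'   \item{eHebb}{terms \{0, 2\}: pseudo-gradient plus the error-Hebbian term.}
#'   \item{Oja}{terms \{0, 9\}: pseudo-gradient plus Oja's rule.}
#'   \item{bio}{terms \{0, 2, 9\}: the sparse rule the full pool converges to.}
#'   \item{pool}{all ten candidate terms.}
#' }
#'
#' @param name one of `"FA_baseline"`, `"bio"`, `"eHebb"`, `"Oja"`, `"pool"`.
#' @return a [plasticity_rule()].
#' @export
named_rule <- function(name = c("FA_baseline", "bio", "eHebb", "Oja", "pool")) {
  name <- match.arg(name)
  active <- switch(name,
    FA_baseline = 0L,
    bio = c(0L, 2L, 9L),
    eHebb = c(0L, 2L),
    Oja = c(0L, 9L),
    pool = 0:9
  )
  theta <- numeric(length(active))
  theta[active == 0] <- 1e-3
  plasticity_rule(active, theta)
}

#' Compose the weight update of one layer
#'
#' `dW = sum_r theta_r F^r(s)` over the rule's active terms; the layer is
#' then updated as `W <- W + dW`. Linear in `theta` by construction.
#'
#' @param coeffs a [plasticity_rule()] (or any list with `theta`, `active`).
#' @param s a [local_signals()] bundle.
#' @return weight-shaped update matrix.
#' @export
compose_update <- function(coeffs, s) {
  dW <- s$W * 0
  for (r in coeffs$active) {
    th <- coeffs$theta[r + 1]
    if (!identical(unname(th), 0)) dW <- dW + th * plasticity_term(r, s)
  }
  dW
}

#' Per-layer rule assignment with shared coefficients
#'
#' Assigns each weight matrix its own set of active terms while all layers
#' share one coefficient vector `theta` (meta-parameter sharing). Used, for
#' example, to train some layers with the feedback-alignment baseline and
#' others with the eHebb rule.
#'
#' @param active_by_layer list of L integer vectors of 0-based term indices,
#'   one per weight matrix.
#' @param theta_init full length-10 coefficient vector, or `NULL` for
#'   `theta_0 = 1e-3` and zeros elsewhere.
#' @return an object of class `layer_rule_map` with fields `theta`,
#'   `active_by_layer`, and `active` (the union, i.e. the meta-learned set).
#' @export
layer_rule_map <- function(active_by_layer, theta_init = NULL) {
  if (!is.list(active_by_layer) || length(active_by_layer) < 1)
    stop("active_by_layer must be a non-empty list")
  active_by_layer <- lapply(active_by_layer, function(a) {
    a <- sort(unique(as.integer(a)))
    if (length(a) == 0 || any(!(a %in% 0:9)))
      stop("each layer's active set must be a non-empty subset of 0..9")
    a
  })
  theta <- stats::setNames(numeric(10), paste0("theta_", 0:9))
  if (is.null(theta_init)) theta[1] <- 1e-3 else theta[] <- theta_init
  structure(list(theta = theta,
                 active_by_layer = active_by_layer,
                 active = sort(unique(unlist(active_by_layer)))),
            class = "layer_rule_map")
}

# Normalize a rule or map to (theta, list of per-layer active sets, active).
.as_rule_set <- function(rule, L) {
  if (inherits(rule, "plasticity_rule")) {
    list(theta = rule$theta,
         active_by_layer = rep(list(rule$active), L),
         active = rule$active)
  } else if (inherits(rule, "layer_rule_map")) {
    if (length(rule$active_by_layer) != L)
      stop(sprintf("layer_rule_map has %d entries for %d weight matrices",
                   length(rule$active_by_layer), L))
    rule[c("theta", "active_by_layer", "active")]
  } else {
    stop("rule must be a plasticity_rule or layer_rule_map")
  }
}

#' @export
print.plasticity_rule <- function(x, ...) {
  cat("<plasticity_rule> active terms:",
      paste(x$active, collapse = ", "), "\n")
  nz <- x$theta[x$active + 1]
  cat("  theta:", paste(sprintf("%s=%.3g", names(nz), nz), collapse = " "),
      "\n")
  invisible(x)
}
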