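# Integrated Gradients attribution over the 30 descriptor positions.

#' Integrated Gradients feature attribution
#'
#' Attributes the model output to each of the 30 input components by
#' integrating the input gradient along the straight path from a baseline to
#' the input, Riemann-approximated at `steps` midpoints:
#' `attr_i = (x_i - b_i) * mean_k d f(b + (k - 1/2)/steps * (x - b)) / d x_i`.
#' Satisfies the completeness axiom: attributions sum to
#' `f(input) - f(baseline)` up to the Riemann error.
#'
#' @param model a differentiable (neural) `flex_model`.
#' @param inputs one input vector or an m x 30 matrix.
#' @param baseline baseline vector (default all zeros).
#' @param steps number of Riemann midpoints.
#' @return m x 30 matrix of attributions (a vector if one input).
#' @export
integrated_gradients <- function(model, inputs, baseline = NULL, steps = 256L) {
  if (model$spec$architecture == "svm_rbf") {
    stop("Integrated Gradients requires a differentiable model", call. = FALSE)
  }
  X <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1L)
  L <- model$spec$input_length
  if (is.null(baseline)) baseline <- numeric(L)
  m <- nrow(X)
  total <- matrix(0, m, L)
  Bmat <- matrix(baseline, m, L, byrow = TRUE)
  D <- X - Bmat
  for (k in seq_len(steps)) {
    Xa <- Bmat + (k - 0.5) / steps * D
    fwd <- nn_forward(model, Xa, keep_cache = TRUE)
    # gradient of the model output (probability or regression value)
    dz <- if (model$spec$task == "classification") {
      fwd$score * (1 - fwd$score)
    } else rep(1, m)
    total <- total + nn_backward(model, fwd, dz)$dX
  }
  attrs <- D * total / steps
  colnames(attrs) <- colnames(X)
  if (!is.matrix(inputs)) attrs[1L, ] else attrs
}
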