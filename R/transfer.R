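#' Transfer-function specification
#'
#' Chooses how a continuous position is mapped to a binary feature mask:
#' either a fixed 0.5 threshold, or one of the eight classical S-/V-shaped
#' transfer functions. S-shaped functions give the probability that a bit is
#' set; V-shaped functions give the probability that the current bit is
#' flipped, so the V family keeps a persistent mask per agent.
#'
#' @param family \code{"threshold"}, \code{"s"} or \code{"v"}.
#' @param variant integer 1..4; ignored for the threshold family.
#' @return an object of class \code{transfer_spec}.
#' @seealso \code{\link{as_transfer_spec}} for the string shorthand
#'   (\code{"threshold"}, \code{"s1"}..\code{"s4"}, \code{"v1"}..\code{"v4"}).
#' @export
transfer_spec <- function(family = c("threshold", "s", "v"), variant = 1L) {
  family <- match.arg(family)
  variant <- as.integer(variant)
  if (family != "threshold" && !(variant %in% 1:4))
    stop("'variant' must be 1, 2, 3 or 4")
  structure(list(family = family,
                 variant = if (family == "threshold") NA_integer_ else variant),
            class = "transfer_spec")
}

#' Parse a transfer-function name
#'
#' @param x a \code{transfer_spec}, or one of \code{"threshold"},
#'   \code{"s1"}..\code{"s4"}, \code{"v1"}..\code{"v4"} (case-insensitive).
#' @return a \code{transfer_spec}.
#' @export
as_transfer_spec <- function(x) {
  if (inherits(x, "transfer_spec")) return(x)
  s <- tolower(as.character(x))
  if (s == "threshold") return(transfer_spec("threshold"))
  if (grepl("^[sv][1-4]$", s))
    return(transfer_spec(substr(s, 1, 1), as.integer(substr(s, 2, 2))))
  stop("unknown transfer function '", x,
       "'; use 'threshold', 's1'..'s4' or 'v1'..'v4'")
}

#' @export
print.transfer_spec <- function(x, ...) {
  cat(if (x$family == "threshold") "transfer: fixed 0.5 threshold\n"
      else sprintf("transfer: %s%d (%s-shaped)\n", toupper(x$family),
                   x$variant, toupper(x$family)))
  invisible(x)
}

#' Threshold binarization
#'
#' Maps a continuous position to a feature mask: bit j is 1 when x_j > 0.5
#' and 0 otherwise (the boundary x = 0.5 maps to 0).
#'
#' @param x numeric vector with finite entries.
#' @return integer 0/1 vector of the same length.
#' @export
threshold_binarize <- function(x) {
  if (!all(is.finite(x))) stop("threshold_binarize: entries must be finite")
  as.integer(x > 0.5)
}

#' S-shaped transfer functions
#'
#' S1(x) = 1/(1+e^-x), S2(x) = 1/(1+e^x), S3(x) = 1/(1+e^(-x/2)),
#' S4(x) = 1/(1+e^(-x/3)). The value is interpreted as the probability of
#' setting the bit to 1.
#'
#' @param x numeric vector.
#' @param variant integer 1..4.
#' @return probabilities in (0, 1).
#' @export
s_transfer <- function(x, variant) {
  switch(as.character(variant),
         "1" = stats::plogis(x),
         "2" = stats::plogis(-x),
         "3" = stats::plogis(x / 2),
         "4" = stats::plogis(x / 3),
         stop("unknown S-shaped variant ", variant))
}

#' V-shaped transfer functions
#'
#' V1(x) = |tanh(x)|, V2(x) = |erf((sqrt(pi)/2) x)|, V3(x) = |x/sqrt(1+x^2)|,
#' V4(x) = |(2/pi) atan((pi/2) x)|. All are symmetric with V(0) = 0; the
#' value is interpreted as the probability of flipping the current bit.
#'
#' @inheritParams s_transfer
#' @return probabilities in \[0, 1).
#' @export
v_transfer <- function(x, variant) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  switch(as.character(variant),
         "1" = abs(tanh(x)),
         "2" = abs(erf(sqrt(pi) / 2 * x)),
         "3" = abs(x / sqrt(1 + x^2)),
         "4" = abs(2 / pi * atan(pi / 2 * x)),
         stop("unknown V-shaped variant ", variant))
}

#' Binarize a continuous position
#'
#' Applies the configured transfer rule to a continuous position.
#' Threshold: deterministic cut at 0.5. S family: bit_j = 1 with probability
#' TF(x_j). V family: the current bit is flipped with probability TF(x_j),
#' so \code{current_bits} is required.
#'
#' @param x numeric position vector.
#' @param spec a \code{\link{transfer_spec}} or its string shorthand.
#' @param current_bits the agent's current mask (V family only).
#' @return integer 0/1 mask.
#' @export
apply_transfer <- function(x, spec, current_bits = NULL) {
  spec <- as_transfer_spec(spec)
  if (spec$family == "threshold") return(threshold_binarize(x))
  if (spec$family == "s") {
    p <- s_transfer(x, spec$variant)
    return(as.integer(stats::runif(length(x)) < p))
  }
  if (is.null(current_bits) || length(current_bits) != length(x))
    stop("V-shaped transfer needs 'current_bits' of the same length as 'x'")
  p <- v_transfer(x, spec$variant)
  flip <- stats::runif(length(x)) < p
  as.integer(ifelse(flip, 1L - current_bits, current_bits))
}
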