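# Closed-form extension predictions for a worm-like chain confined in a
# channel/stripe of width w, and the classification of the confinement
# regime from the ratio of persistence length to width.

#' Contour length of a discrete chain
#'
#' lc = n_monomers * spacing.  The monomer count (not the bond count)
#' multiplies the spacing, matching the convention under which the
#' confinement predictions below reproduce the reference values for a
#' 20-mer with a = 0.625 nm.
#'
#' @param n_monomers Number of monomers.
#' @param spacing Monomer spacing a in nm.
#' @return Contour length in nm.
#' @examples
#' contour_length(20, 0.625)   # 12.5 nm
#' @export
contour_length <- function(n_monomers, spacing) {
  stopifnot(n_monomers >= 1, spacing > 0)
  n_monomers * spacing
}

#' Gauss–de Gennes extension in a channel
#'
#' Blob-picture prediction for the end-to-end extension of a weakly
#' confined chain: lc * lp / w.
#'
#' @param lc Contour length, nm.
#' @param lp Persistence length, nm.
#' @param w Channel/stripe width, nm.
#' @return Predicted extension in nm.
#' @examples
#' degennes_extension(12.5, 1.39, 1.8)   # 9.653 nm = 96.5 A
#' @export
degennes_extension <- function(lc, lp, w) {
  stopifnot(lc > 0, lp > 0, w > 0)
  lc * lp / w
}

#' Odijk deflection-segment extension in a channel
#'
#' Strong-confinement prediction lc * (1 - A (lp/w)^(-2/3)) with the
#' universal prefactor A = 0.17.
#'
#' @inheritParams degennes_extension
#' @param A Universal prefactor (default 0.17).
#' @return Predicted extension in nm.  Errors if the bracket is
#'   non-positive (the deflection picture does not apply).
#' @examples
#' odijk_extension(12.5, 1.39, 1.8)   # 9.975 nm = 99.8 A
#' @export
odijk_extension <- function(lc, lp, w, A = 0.17) {
  stopifnot(lc > 0, lp > 0, w > 0, A >= 0)
  frac <- 1 - A * (lp / w)^(-2 / 3)
  if (frac <= 0) {
    stop("Odijk extension non-positive: A*(lp/w)^(-2/3) = ",
         signif(1 - frac, 3), " >= 1; regime inapplicable")
  }
  lc * frac
}

#' Classify the confinement regime
#'
#' Odijk (deflection) regime for w <= lp; transition for
#' lp < w < 2 lp; Gauss–de Gennes (blob) regime for w >= 2 lp.
#' Boundary ties go to the adjacent named regime, as only the open
#' interval defines the transition.
#'
#' @param lp Persistence length, nm.
#' @param w Channel width, nm.
#' @return `"odijk"`, `"transition"` or `"degennes"`.
#' @examples
#' classify_regime(1.39, 1.8)   # "transition"
#' @export
classify_regime <- function(lp, w) {
  stopifnot(lp > 0, w > 0)
  if (w <= lp) "odijk" else if (w < 2 * lp) "transition" else "degennes"
}

#' Confinement-theory summary for a chain in a stripe
#'
#' Computes the contour length, both closed-form extension predictions
#' and the regime label for a chain of `n` monomers at spacing `a` with
#' persistence length `lp` in a stripe of width `w`.
#'
#' @param n Monomer count.
#' @param a Monomer spacing, nm.
#' @param lp Persistence length, nm.
#' @param w Stripe width, nm.
#' @param A Odijk prefactor.
#' @return A one-row tibble: `lc`, `lp`, `w`, `prefactor_A`,
#'   `degennes_extension`, `odijk_extension` (nm) and `regime`.
#' @examples
#' confinement_theory()   # defaults: the 20-mer on a 1.8-nm stripe
#' @export
confinement_theory <- function(n = 20, a = 0.625, lp = 1.39, w = 1.8,
                               A = 0.17) {
  lc <- contour_length(n, a)
  tibble::tibble(
    lc = lc, lp = lp, w = w, prefactor_A = A,
    degennes_extension = degennes_extension(lc, lp, w),
    odijk_extension = odijk_extension(lc, lp, w, A),
    regime = classify_regime(lp, w)
  )
}
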