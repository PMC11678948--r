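# Daubechies-4 (8-tap) scaling filter, orthonormal (sums to sqrt(2)).
DB4_H <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
           -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)
DB4_G <- rev(DB4_H) * (-1)^(seq_along(DB4_H) - 1L)

# One periodic filtering + dyadic downsampling step.
wpt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  # y[k] = sum_l filt[l] * x[(2k - 1 + l - 1) mod n + 1], k = 1..n/2
  idx <- outer(2 * seq_len(n %/% 2) - 2L, seq_len(L) - 1L, "+") %% n + 1L
  as.numeric(matrix(x[idx], ncol = L) %*% filt)
}

#' Wavelet packet sub-band energies
#'
#' Full wavelet packet decomposition of a signal with the Daubechies-4
#' filter pair and periodic extension, to `levels` levels, giving
#' `2^levels` leaf sub-bands in natural (filter-order) arrangement. Returns
#' the relative energy of each leaf; by orthonormality these sum to the
#' signal's total energy before normalization, hence to 1 after. A
#' zero-energy signal is treated as pure DC: all energy assigned to the first
#' (all-lowpass) band.
#'
#' @param x numeric signal; length must be divisible by `2^levels`.
#' @param levels decomposition depth (default 3, i.e. 8 sub-bands).
#' @return Numeric vector of `2^levels` relative energies summing to 1.
#' @export
wpt_band_energies <- function(x, levels = 3) {
  n <- length(x)
  if (n %% 2^levels != 0) stop("signal length must be divisible by 2^levels")
  nodes <- list(x)
  for (lv in seq_len(levels)) {
    nodes <- unlist(lapply(nodes, function(node) {
      list(wpt_step(node, DB4_H), wpt_step(node, DB4_G))
    }), recursive = FALSE)
  }
  e <- vapply(nodes, function(node) sum(node^2), numeric(1))
  total <- sum(e)
  if (total < .Machine$double.xmin) return(c(1, rep(0, length(e) - 1L)))
  e / total
}
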