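#' One-dimensional free-energy profile
#'
#' @param distance Strictly increasing distance grid (Angstrom).
#' @param free_energy Free energy (kJ/mol), finite.
#' @param std Optional per-point standard deviation (kJ/mol).
#' @return Object of class `fes_profile`.
#' @export
free_energy_profile <- function(distance, free_energy, std = NULL) {
  stop_if(any(diff(distance) <= 0), "distance grid must be strictly increasing")
  stop_if(length(distance) != length(free_energy), "grid/energy length mismatch")
  stop_if(any(!is.finite(free_energy)), "free energies must be finite")
  structure(list(distance = as.numeric(distance),
                 free_energy = as.numeric(free_energy),
                 std = if (is.null(std)) NULL else as.numeric(std)),
            class = "fes_profile")
}

#' Detect basins on a free-energy profile
#'
#' Finds interior local minima, computes the prominence of each (the lower
#' of the two barrier heights that must be climbed before reaching a deeper
#' point), keeps minima with prominence at or above `min_prominence`, and
#' assigns watershed boundaries at the separating maxima (profile ends for
#' the outermost basins). A monotone profile yields an empty result.
#'
#' @param profile A [free_energy_profile()] with >= 10 points.
#' @param min_prominence Minimum prominence (kJ/mol), default 2.
#' @return data.frame sorted by position: `position`, `depth` (energy at the
#'   minimum), `left`, `right` (boundaries, Angstrom), `prominence`.
#' @export
find_basins <- function(profile, min_prominence = 2) {
  d <- profile$distance
  F <- profile$free_energy
  n <- length(F)
  stop_if(n < 10, "need >= 10 grid points")
  empty <- data.frame(position = numeric(0), depth = numeric(0),
                      left = numeric(0), right = numeric(0),
                      prominence = numeric(0))

  # interior local minima (plateau-aware: strict drop on both flanks)
  is_min <- logical(n)
  for (i in 2:(n - 1)) {
    if (F[i] > F[i - 1] || F[i] > F[i + 1]) next
    j <- i
    while (j > 1 && F[j - 1] == F[i]) j <- j - 1
    k <- i
    while (k < n && F[k + 1] == F[i]) k <- k + 1
    if (j > 1 && k < n && F[j - 1] > F[i] && F[k + 1] > F[i]) is_min[i] <- TRUE
  }
  cand <- which(is_min)
  if (length(cand) == 0) return(empty)

  prominence <- vapply(cand, function(i) {
    side <- function(idx_range) {
      if (length(idx_range) == 0) return(Inf)
      barrier <- -Inf
      for (j in idx_range) {
        barrier <- max(barrier, F[j])
        if (F[j] < F[i]) return(barrier - F[i])
      }
      barrier - F[i]   # reached the edge without finding a deeper point
    }
    min(side(rev(seq_len(i - 1))), side(seq(i + 1, n)))
  }, 1)

  keep <- cand[prominence >= min_prominence]
  prom <- prominence[prominence >= min_prominence]
  if (length(keep) == 0) return(empty)

  # watershed boundaries at separating maxima
  left <- right <- numeric(length(keep))
  for (b in seq_along(keep)) {
    left[b] <- if (b == 1) d[1] else {
      seg <- keep[b - 1]:keep[b]
      d[seg[which.max(F[seg])]]
    }
    right[b] <- if (b == length(keep)) d[n] else {
      seg <- keep[b]:keep[b + 1]
      d[seg[which.max(F[seg])]]
    }
  }
  data.frame(position = d[keep], depth = F[keep], left = left, right = right,
             prominence = prom)
}

# Gas constant in kJ mol^-1 K^-1.
R_KJ <- 8.314462618e-3

#' Boltzmann populations of detected basins
#'
#' \deqn{p_b = \int_b e^{-F(d)/RT} dd \,/\, \sum_{b'} \int_{b'} e^{-F/RT} dd}
#' with the profile shifted so its global minimum is zero (overflow guard);
#' trapezoidal quadrature on the profile grid.
#'
#' @param profile A [free_energy_profile()].
#' @param basins data.frame from [find_basins()] (needs `left`, `right`).
#' @param temperature Temperature (K), default 298.
#' @return Numeric fractions, one per basin, summing to 1.
#' @export
boltzmann_populations <- function(profile, basins, temperature = 298) {
  stop_if(nrow(basins) == 0, "empty basin list")
  d <- profile$distance
  F <- profile$free_energy - min(profile$free_energy)
  w <- exp(-F / (R_KJ * temperature))
  ints <- vapply(seq_len(nrow(basins)), function(b) {
    sel <- d >= basins$left[b] & d <= basins$right[b]
    pracma::trapz(d[sel], w[sel])
  }, 1)
  ints / sum(ints)
}

#' Classify basins by dye stacking geometry
#'
#' Center-of-mass separations at or below 5 Angstrom are labelled fully
#' pi-`stacked`, up to 12 Angstrom `slipped` (slipped-stacked), and beyond
#' that `distal`. The thresholds bracket the canonical 3.5 and 10.0
#' Angstrom stacking distances with margin.
#'
#' @param basins data.frame with a `position` column (Angstrom).
#' @param stacked_max,slipped_max Class boundaries (Angstrom).
#' @return Character vector of labels.
#' @export
classify_states <- function(basins, stacked_max = 5, slipped_max = 12) {
  ifelse(basins$position <= stacked_max, "stacked",
         ifelse(basins$position <= slipped_max, "slipped", "distal"))
}
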