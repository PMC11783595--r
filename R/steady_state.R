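# Integrated band area of a spectrum within +/- half_width nm of a center.
band_area <- function(s, center, half_width = 40) {
  sel <- s$wavelengths >= center - half_width & s$wavelengths <= center + half_width
  stop_if(sum(sel) < 2, "band outside the spectrum grid")
  pracma::trapz(s$wavelengths[sel], s$values[sel])
}

#' Non-negative spectral unmixing
#'
#' Decomposes a mixed emission spectrum as a nonnegative linear combination
#' of reference spectra (interpolated onto the mixed grid), by non-negative
#' least squares. Near-collinear references are flagged but coefficients are
#' still returned.
#'
#' @param mixed [spectrum()] to decompose.
#' @param references List of reference [spectrum()]s.
#' @return List: `coefficients`, `residual_norm`, `collinear` (logical).
#' @export
unmix_spectrum <- function(mixed, references) {
  stop_if(length(references) < 1, "need at least one reference")
  A <- vapply(references, interp_spectrum, grid = mixed$wavelengths,
              FUN.VALUE = numeric(length(mixed$wavelengths)))
  A <- matrix(A, ncol = length(references))
  collinear <- FALSE
  if (ncol(A) > 1) {
    sv <- svd(scale(A, center = FALSE,
                    scale = sqrt(colSums(A^2)) + 1e-300))$d
    collinear <- sv[length(sv)] < 1e-6 * sv[1]
    if (collinear) warning("reference spectra are nearly collinear")
  }
  sol <- pracma::lsqnonneg(A, mixed$values)
  list(coefficients = as.numeric(sol$x),
       residual_norm = sqrt(sum((A %*% sol$x - mixed$values)^2)),
       collinear = collinear)
}

#' Apparent steady-state FRET efficiency
#'
#' Ratiometric sensitized-acceptor estimator: the mixed spectrum is unmixed
#' against the donor-only and acceptor-only references; the sensitized
#' acceptor signal is the acceptor coefficient times the acceptor band area
#' minus the direct-excitation contribution, and
#' \eqn{E_{app} = sensitized / (sensitized + donor signal)}, clamped to
#' \[0, 1\]. Band areas integrate +/- 40 nm around the 450 nm donor and
#' 593 nm acceptor reference peaks.
#'
#' @param donor_only,acceptor_only,mixed Emission [spectrum()]s on
#'   overlapping grids.
#' @param direct_excitation_fraction Fraction of the acceptor-only band area
#'   expected from direct acceptor excitation (default 0).
#' @param donor_band_nm,acceptor_band_nm Band centers (nm).
#' @return Apparent efficiency in \[0, 1\], with attributes `donor_signal`
#'   and `acceptor_signal`.
#' @export
apparent_fret_efficiency <- function(donor_only, acceptor_only, mixed,
                                     direct_excitation_fraction = 0,
                                     donor_band_nm = 450,
                                     acceptor_band_nm = 593) {
  um <- unmix_spectrum(mixed, list(donor_only, acceptor_only))
  bd <- band_area(donor_only, donor_band_nm)
  ba <- band_area(acceptor_only, acceptor_band_nm)
  donor_signal <- um$coefficients[1] * bd
  sensitized <- um$coefficients[2] * ba - direct_excitation_fraction * ba
  total <- sensitized + donor_signal
  stop_if(total <= 0, "zero total signal in both bands")
  e <- min(max(sensitized / total, 0), 1)
  attr(e, "donor_signal") <- donor_signal
  attr(e, "acceptor_signal") <- sensitized
  e
}

#' Screen a panel of peptides for FRET
#'
#' Computes the apparent FRET efficiency for each panel and returns results
#' ranked by descending efficiency (ties broken by peptide id). A panel is
#' positive when its efficiency meets the threshold.
#'
#' @param panels List of panels, each a list with `peptide_id`,
#'   `donor_only`, `acceptor_only`, `mixed` (see
#'   [simulate_screen_panels()]).
#' @param threshold Positive-call threshold on e_app (default 0.1).
#' @param direct_excitation_fraction Passed to
#'   [apparent_fret_efficiency()].
#' @return data.frame with `peptide_id`, `e_app`, `positive`,
#'   `donor_signal`, `acceptor_signal`, ranked.
#' @export
screen_panel <- function(panels, threshold = 0.1,
                         direct_excitation_fraction = 0) {
  stop_if(length(panels) < 1, "need at least one panel")
  ids <- vapply(panels, `[[`, "", "peptide_id")
  stop_if(anyDuplicated(ids) > 0, "duplicate peptide_id in panel")
  rows <- lapply(panels, function(p) {
    e <- apparent_fret_efficiency(p$donor_only, p$acceptor_only, p$mixed,
                                  direct_excitation_fraction)
    data.frame(peptide_id = p$peptide_id, e_app = as.numeric(e),
               positive = as.numeric(e) >= threshold,
               donor_signal = attr(e, "donor_signal"),
               acceptor_signal = attr(e, "acceptor_signal"))
  })
  out <- do.call(rbind, rows)
  out[order(-out$e_app, out$peptide_id), , drop = FALSE]
}

#' Fit a ligand-depletion binding isotherm
#'
#' Weighted least-squares fit of
#' \eqn{F/F_{max} = f_0 + (f_{max} - f_0)\, \theta(P; K_d, L)} where theta is
#' the single-site quadratic bound fraction with explicit ligand depletion.
#' Standard errors are asymptotic (from the Jacobian at the optimum). When
#' the Kd standard error exceeds the estimate the fit is flagged
#' unidentifiable.
#'
#' @param series A [binding_series()] (see [simulate_titration()]), or a
#'   data.frame with `conc_uM`, `f_norm` and attribute `ligand_total`.
#' @param ligand_total Total ligand (uM); defaults to the series attribute.
#' @param weights Optional per-point weights (default 1).
#' @return List: `kd`, `f0`, `fmax`, `se` (named), `reduced_chi2`,
#'   `identifiable`, `fit`.
#' @export
fit_binding <- function(series, ligand_total = attr(series, "ligand_total"),
                        weights = NULL) {
  conc <- series$conc_uM
  f <- series$f_norm
  stop_if(length(unique(conc)) < 5 || !any(conc == 0),
          "need >= 5 distinct concentrations including 0")
  if (is.null(ligand_total)) ligand_total <- 0.5
  if (is.null(weights)) weights <- rep(1, length(f))
  resid_fn <- function(par) {
    kd <- exp(par[1])
    pred <- par[2] + (par[3] - par[2]) *
      bound_fraction_depletion(conc, ligand_total, kd)
    (pred - f) * sqrt(weights)
  }
  p0 <- c(log(max(stats::median(conc), 1)), min(f), max(f))
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  stop_if(!(fit$info %in% 1:4),
          paste("binding fit did not converge; last iterate kd =",
                signif(exp(fit$par[1]), 4)))
  par <- fit$par
  n <- length(f)
  dof <- max(n - 3, 1)
  s2 <- sum(fit$fvec^2) / dof
  cov <- tryCatch(s2 * solve(fit$hessian),
                  error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cov), 0))
  kd <- exp(par[1])
  kd_se <- kd * se[1]
  list(kd = kd, f0 = par[2], fmax = par[3],
       se = c(kd = kd_se, f0 = se[2], fmax = se[3]),
       reduced_chi2 = s2,
       identifiable = is.finite(kd_se) && kd_se < kd,
       fit = fit)
}

#' Detect competitive displacement between two titrations
#'
#' Compares the saturating-region (top quartile of the concentration grid)
#' mean normalized fluorescence of a dye titrated alone against the same
#' titration in the presence of a competitor. Displacement is called when
#' the competitor series falls below `(1 - drop_threshold)` times the
#' single-dye level.
#'
#' @param single_dye,with_competitor [binding_series()] on matched grids.
#' @param drop_threshold Fractional drop calling displacement (default 0.5,
#'   a "strong decrease").
#' @return List: `displaced` (logical), `drop` (observed fractional drop),
#'   `single_plateau`, `competitor_plateau`.
#' @export
detect_displacement <- function(single_dye, with_competitor,
                                drop_threshold = 0.5) {
  g1 <- sort(unique(single_dye$conc_uM))
  g2 <- sort(unique(with_competitor$conc_uM))
  stop_if(length(g1) != length(g2) || any(abs(g1 - g2) > 1e-9),
          "concentration grids must match")
  cutoff <- stats::quantile(g1, 0.75)
  p1 <- mean(single_dye$f_norm[single_dye$conc_uM >= cutoff])
  p2 <- mean(with_competitor$f_norm[with_competitor$conc_uM >= cutoff])
  drop <- 1 - p2 / p1
  list(displaced = p2 < (1 - drop_threshold) * p1, drop = drop,
       single_plateau = p1, competitor_plateau = p2)
}
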