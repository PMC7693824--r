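## Per-peptide physicochemical panel: average mass with C-terminal amidation,
## formal and Henderson-Hasselbalch net charge, isoelectric point, GRAVY,
## hydrophobic residue fraction, Eisenberg hydrophobic moment, helical-wheel
## geometry, and MIC unit conversion.

#' Average molecular mass of a peptide
#'
#' Sums isotope-averaged residue masses plus one water; an amidated
#' C-terminus (NH2 replacing OH) subtracts [AMIDATION_DELTA] (0.9847 Da).
#'
#' @param sequence Residue string.
#' @param amidated Is the C-terminus amidated?
#' @return Mass in daltons (full precision; report to 2 decimals).
#' @examples
#' round(average_mass("GVLDIFKDAAKQILAHAAEKI", amidated = TRUE), 2)  # 2250.67
#' @export
average_mass <- function(sequence, amidated = FALSE) {
  res <- check_residues(sequence)
  m <- sum(AA_MASS_AVG[res]) + WATER_MASS
  if (isTRUE(amidated)) m <- m - AMIDATION_DELTA
  m
}

#' Formal net charge at pH 7
#'
#' Integer charge model: +1 for the free N-terminus, +1 per Lys/Arg, -1 per
#' Asp/Glu, -1 for the free-acid C-terminus (dropped when amidated). His
#' contributes 0 at pH 7 in this formal count; the continuous model
#' ([net_charge_continuous()]) gives it pKa 6.0 instead.
#'
#' @inheritParams average_mass
#' @return Integer net charge.
#' @examples
#' net_charge_formal("GVVDILKDTGKKLLSHLMEKI", amidated = TRUE)  # +2
#' @export
net_charge_formal <- function(sequence, amidated = FALSE) {
  res <- check_residues(sequence)
  plus <- 1L + sum(res %in% c("K", "R"))
  minus <- sum(res %in% c("D", "E")) + if (isTRUE(amidated)) 0L else 1L
  as.integer(plus - minus)
}

ionizable_groups <- function(res, amidated) {
  counts <- c(
    Nterm = 1, K = sum(res == "K"), R = sum(res == "R"), H = sum(res == "H"),
    Cterm = if (isTRUE(amidated)) 0 else 1,
    D = sum(res == "D"), E = sum(res == "E"),
    C = sum(res == "C"), Y = sum(res == "Y")
  )
  counts[counts > 0]
}

POSITIVE_GROUPS <- c("Nterm", "K", "R", "H")

#' Continuous net charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups using the documented
#' [PKA_SET]: basic groups (N-terminus, Lys, Arg, His) contribute
#' `+1 / (1 + 10^(pH - pKa))`, acidic groups (C-terminus, Asp, Glu, Cys, Tyr)
#' contribute `-1 / (1 + 10^(pKa - pH))`. Strictly decreasing in pH.
#'
#' @inheritParams average_mass
#' @param pH pH value in `[0, 14]`.
#' @return Net charge (float).
#' @export
net_charge_continuous <- function(sequence, amidated = FALSE, pH = 7) {
  if (!is.numeric(pH) || pH < 0 || pH > 14) stop("pH must be in [0, 14]",
                                                 call. = FALSE)
  res <- check_residues(sequence)
  groups <- ionizable_groups(res, amidated)
  q <- 0
  for (g in names(groups)) {
    pka <- PKA_SET[[g]]
    q <- q + if (g %in% POSITIVE_GROUPS) {
      groups[[g]] / (1 + 10^(pH - pka))
    } else {
      -groups[[g]] / (1 + 10^(pka - pH))
    }
  }
  q
}

#' Isoelectric point
#'
#' Finds the pH where the continuous net charge vanishes, by bisection on
#' `[0, 14]` to `|charge| < tol`. The charge function is strictly monotone,
#' so the root is unique; peptides whose charge does not change sign over the
#' pH scale (none with a free N-terminus) raise an error.
#'
#' @inheritParams average_mass
#' @param tol Convergence tolerance on the charge.
#' @return pI in pH units.
#' @export
compute_pI <- function(sequence, amidated = FALSE, tol = 1e-4) {
  f <- function(p) net_charge_continuous(sequence, amidated, p)
  lo <- 0; hi <- 14
  if (f(lo) < 0 || f(hi) > 0) stop("charge does not change sign on [0, 14]",
                                   call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- f(mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection did not converge", call. = FALSE)  # nocov
}

#' GRAVY: grand average of hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over the sequence; positive values are
#' hydrophobic.
#'
#' @inheritParams average_mass
#' @return Mean hydropathy (report to 3 decimals).
#' @examples
#' gravy("GG")  # -0.4
#' @export
gravy <- function(sequence) {
  res <- check_residues(sequence)
  mean(KD_HYDROPATHY[res])
}

#' Hydrophobic residue percentage
#'
#' Fraction of residues in [HYDROPHOBIC_SET], expressed as an integer
#' percent truncated toward zero (9/21 -> 42, 11/21 -> 52).
#'
#' @inheritParams average_mass
#' @return Integer percent in `[0, 100]`.
#' @export
hydrophobic_fraction <- function(sequence) {
  res <- check_residues(sequence)
  as.integer(100 * sum(res %in% HYDROPHOBIC_SET) / length(res))
}

#' Eisenberg hydrophobic moment (per residue)
#'
#' Magnitude of the vector sum of Kyte-Doolittle hydropathies placed at
#' `delta` degrees per residue around an ideal alpha-helix (100 deg/residue),
#' divided by the number of residues. Measures amphipathicity: a uniform
#' helix scores near 0, a perfectly segregated one scores high.
#'
#' @inheritParams average_mass
#' @param delta Rotation per residue in degrees.
#' @return Nonnegative moment per residue.
#' @export
hydrophobic_moment <- function(sequence, delta = 100) {
  res <- check_residues(sequence)
  if (length(res) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  h <- KD_HYDROPATHY[res]
  ang <- (seq_along(res) - 1L) * delta * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(res)
}

#' Helical-wheel projection table
#'
#' Schiffer-Edmundson wheel geometry: residue `i` sits at angle
#' `(i - 1) * delta mod 360`; the face label is `hydrophobic` for residues in
#' [HYDROPHOBIC_SET], `hydrophilic` otherwise. The table is the numeric
#' backbone of a wheel plot.
#'
#' @inheritParams hydrophobic_moment
#' @return data.frame with `position`, `residue`, `angle` (degrees), `face`.
#' @export
helical_wheel <- function(sequence, delta = 100) {
  res <- check_residues(sequence)
  if (length(res) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  data.frame(
    position = seq_along(res),
    residue = res,
    angle = ((seq_along(res) - 1L) * delta) %% 360,
    face = ifelse(res %in% HYDROPHOBIC_SET, "hydrophobic", "hydrophilic"),
    stringsAsFactors = FALSE
  )
}

#' Convert MIC between ug/mL and uM
#'
#' `uM = 1000 * (ug/mL) / Mw`; the inverse converts back. Values are
#' returned at full precision; the printed tables round to integers.
#'
#' @param value Concentration (> 0).
#' @param mw Peptide mass in daltons (> 0).
#' @param from Unit of `value`: `"ug_ml"` or `"um"`.
#' @return Converted concentration.
#' @examples
#' round(mic_convert(32, 2273.77))  # 14
#' @export
mic_convert <- function(value, mw, from = c("ug_ml", "um")) {
  from <- match.arg(from)
  if (!is.numeric(value) || any(value <= 0)) stop("value must be > 0",
                                                  call. = FALSE)
  if (!is.numeric(mw) || any(mw <= 0)) stop("mw must be > 0", call. = FALSE)
  if (from == "ug_ml") 1000 * value / mw else value * mw / 1000
}

#' Full physicochemical profile of a peptide
#'
#' @inheritParams average_mass
#' @param pH pH for the continuous charge.
#' @return One-row data.frame: `mw`, `net_charge_formal`,
#'   `net_charge_continuous`, `pI`, `gravy`, `hydrophobic_pct`, `mu_h`.
#' @export
physchem_profile <- function(sequence, amidated = FALSE, pH = 7) {
  data.frame(
    mw = average_mass(sequence, amidated),
    net_charge_formal = net_charge_formal(sequence, amidated),
    net_charge_continuous = net_charge_continuous(sequence, amidated, pH),
    pI = compute_pI(sequence, amidated),
    gravy = gravy(sequence),
    hydrophobic_pct = hydrophobic_fraction(sequence),
    mu_h = hydrophobic_moment(sequence)
  )
}
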