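#' Dye-labeling constants
#'
#' Spectrophotometric constants for Cy5-labeled RNA: the dye extinction
#' coefficient at its 649 nm absorbance maximum, the average per-nucleotide
#' RNA extinction coefficient, and the fraction of dye absorbance that bleeds
#' into the 260 nm reading (the A260 correction factor).
#'
#' @param e_dye Dye extinction coefficient, 1/(M cm). Default 250000 (Cy5).
#' @param e_base RNA per-base extinction coefficient, 1/(M cm). Default 8250.
#' @param cf260 Dye correction factor at 260 nm. Default 0.05 (Cy5).
#' @return A named list.
#' @export
labeling_constants <- function(e_dye = 250000, e_base = 8250, cf260 = 0.05) {
  check_number(e_dye, "e_dye", min = 0, strict = TRUE)
  check_number(e_base, "e_base", min = 0, strict = TRUE)
  check_number(cf260, "cf260", min = 0)
  list(e_dye = e_dye, e_base = e_base, cf260 = cf260)
}

#' Dye density: picomoles of dye per microgram of RNA
#'
#' Beer-Lambert with a 1 cm-equivalent normalized absorbance: the dye
#' concentration is `a_dye / e_dye` mol/L, which over the solution volume
#' gives the picomoles of dye, divided by the RNA mass. A labeling protocol
#' for array probing typically targets about 3 pmol dye per microgram RNA.
#' Absorbance is a concentration, not an amount, so the solution volume enters
#' explicitly; 16 microliters is the default resuspension volume of the
#' labeling protocol.
#'
#' @param a_dye Dye absorbance at its excitation maximum (649 nm for Cy5),
#'   normalized to a 1 cm path.
#' @param mass_ug RNA amount in micrograms.
#' @param volume_ul Solution volume in microliters (default 16).
#' @param constants See [labeling_constants()].
#' @return pmol dye per microgram RNA (vectorized).
#' @export
#' @examples
#' dye_density(a_dye = 0.234, mass_ug = 5, volume_ul = 16) # ~3 pmol/ug
dye_density <- function(a_dye, mass_ug, volume_ul = 16,
                        constants = labeling_constants()) {
  if (!is.numeric(a_dye) || any(!is.finite(a_dye)) || any(a_dye < 0)) {
    stop_input("`a_dye` must be finite and >= 0.")
  }
  if (!is.numeric(mass_ug) || any(!is.finite(mass_ug)) || any(mass_ug <= 0)) {
    stop_input("`mass_ug` must be > 0.")
  }
  if (!is.numeric(volume_ul) || any(!is.finite(volume_ul)) || any(volume_ul <= 0)) {
    stop_input("`volume_ul` must be > 0.")
  }
  # mol/L * uL = mol * 1e-6; * 1e12 pmol/mol => * 1e6
  (a_dye / constants$e_dye) * volume_ul * 1e6 / mass_ug
}

#' Base:Dye ratio — nucleotides per attached dye molecule
#'
#' The RNA base absorbance is the 260 nm reading corrected for dye
#' bleed-through, `A_base = A260 - A_dye * CF260`; the ratio of base to dye
#' molar concentrations is then `(A_base * e_dye) / (A_dye * e_base)`. A
#' sparsely labeled RNA (large ratio) keeps its native structure; a heavily
#' labeled one may not.
#'
#' @param a260 Nucleic-acid absorbance at 260 nm.
#' @param a_dye Dye absorbance at its excitation maximum.
#' @param constants See [labeling_constants()].
#' @return Nucleotides per dye molecule (vectorized).
#' @export
#' @examples
#' base_dye_ratio(a260 = 0.843, a_dye = 0.03) # 850 nt per dye
base_dye_ratio <- function(a260, a_dye, constants = labeling_constants()) {
  if (!is.numeric(a260) || any(!is.finite(a260)) || any(a260 < 0)) {
    stop_input("`a260` must be finite and >= 0.")
  }
  if (!is.numeric(a_dye) || any(!is.finite(a_dye))) {
    stop_input("`a_dye` must be finite.")
  }
  if (any(a_dye <= 0)) {
    stop_input("`a_dye` must be > 0: RNA appears unlabeled.",
               class = "rbpscreen_unlabeled_error")
  }
  a_base <- a260 - a_dye * constants$cf260
  if (any(a_base < 0)) {
    stop_input("corrected base absorbance is negative; check A260 and A_dye.")
  }
  (a_base * constants$e_dye) / (a_dye * constants$e_base)
}

#' Does a labeling reaction pass the efficacy window?
#'
#' The protocol accepts one dye per 700-1200 nucleotides of RNA: enough dye to
#' see the probe on the scanner, sparse enough not to disturb RNA structure.
#' Both bounds are inclusive.
#'
#' @param base_dye Base:Dye ratio from [base_dye_ratio()].
#' @param low,high Acceptance window (defaults 700 and 1200).
#' @return Logical (vectorized).
#' @export
labeling_pass <- function(base_dye, low = 700, high = 1200) {
  check_number(low, "low", min = 0, strict = TRUE)
  check_number(high, "high", min = 0, strict = TRUE)
  if (low >= high) stop_param("`low` must be smaller than `high`.")
  if (!is.numeric(base_dye) || any(!is.finite(base_dye)) || any(base_dye <= 0)) {
    stop_input("`base_dye` must be > 0.")
  }
  base_dye >= low & base_dye <= high
}

#' Labeling QC for a batch of RNAs
#'
#' Takes one row per labeled RNA (as in a spectrophotometer export:
#' `a260`, `a_dye`, `mass_ug` and optionally `volume_ul`, `id`) and appends
#' `dye_density`, `base_dye` and `pass`. Rows with unusable readings
#' (`a_dye <= 0`, negative corrected base absorbance, non-positive mass or
#' volume) get `NA` results and a warning instead of failing the batch.
#'
#' @param df Data frame of measurements.
#' @param low,high Acceptance window passed to [labeling_pass()].
#' @param constants See [labeling_constants()].
#' @return `df` as a tibble with `dye_density`, `base_dye`, `pass` appended.
#' @export
labeling_qc <- function(df, low = 700, high = 1200,
                        constants = labeling_constants()) {
  if (!inherits(df, "data.frame")) stop_input("`df` must be a data frame.")
  need <- c("a260", "a_dye", "mass_ug")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_input(paste0("`df` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (!"volume_ul" %in% names(df)) df$volume_ul <- 16
  a_base <- df$a260 - df$a_dye * constants$cf260
  ok <- is.finite(df$a260) & is.finite(df$a_dye) & df$a_dye > 0 &
    a_base >= 0 & is.finite(df$mass_ug) & df$mass_ug > 0 &
    is.finite(df$volume_ul) & df$volume_ul > 0
  if (any(!ok)) {
    lab <- if ("id" %in% names(df)) df$id[!ok] else which(!ok)
    warn(sprintf("%d row(s) with unusable readings set to NA: %s",
                 sum(!ok), compact_ids(as.character(lab))))
  }
  df$dye_density <- ifelse(ok, (df$a_dye / constants$e_dye) * df$volume_ul * 1e6 / df$mass_ug, NA_real_)
  df$base_dye <- ifelse(ok, (a_base * constants$e_dye) / (df$a_dye * constants$e_base), NA_real_)
  df$pass <- ifelse(ok, df$base_dye >= low & df$base_dye <= high, NA)
  df
}
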