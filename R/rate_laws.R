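#' ATP-depletion model: oxygen to ATP mapping
#'
#' Parameters of the hyperbolic (Michaelis-Menten form) relationship between
#' the ambient oxygen level, expressed as a fraction of normoxia, and the
#' cellular ATP concentration. ATP homeostasis keeps ATP near its normoxic
#' value until oxygen falls to a few percent of normoxia; the half-maximal
#' ATP level occurs at 3.3% of normoxic oxygen.
#'
#' @param atp_normoxia Maximal (normoxic) ATP concentration, in micromolar.
#'   Default 3000.
#' @param half_max_o2_fraction Oxygen fraction (of normoxia) at which ATP is
#'   half-maximal. Default 0.033.
#' @return An object of class `atp_model`.
#' @export
atp_model <- function(atp_normoxia = 3000, half_max_o2_fraction = 0.033) {
  stopifnot(is.numeric(atp_normoxia), length(atp_normoxia) == 1L, atp_normoxia > 0,
            is.numeric(half_max_o2_fraction), length(half_max_o2_fraction) == 1L,
            half_max_o2_fraction > 0)
  structure(list(atp_normoxia = atp_normoxia,
                 half_max_o2_fraction = half_max_o2_fraction),
            class = "atp_model")
}

#' Cellular ATP level at a given oxygen fraction
#'
#' `[ATP] = [ATP]_normoxia * f / (h + f)` where `f` is oxygen as a fraction of
#' normoxia and `h` is the half-maximal fraction. Strictly increasing in `f`
#' and bounded above by `atp_normoxia`.
#'
#' @param o2_fraction Oxygen as a fraction of normoxia, in (0, 1]. Vectorized.
#' @param model An [atp_model()].
#' @return ATP concentration(s) in the units of `model$atp_normoxia`
#'   (micromolar by default).
#' @examples
#' atp_level(0.033)  # exactly half of 3000
#' @export
atp_level <- function(o2_fraction, model = atp_model()) {
  if (!is.numeric(o2_fraction) || any(!is.finite(o2_fraction)) || any(o2_fraction <= 0)) {
    stop("o2_fraction must be finite and > 0", call. = FALSE)
  }
  model$atp_normoxia * o2_fraction / (model$half_max_o2_fraction + o2_fraction)
}

#' Calibrate the protein-substrate dissociation constant K^AB
#'
#' The ATP-explicit phosphorylation law uses an effective substrate constant
#' `(K_M,ATP/[ATP] + 1) * K^AB`. To leave the original (ATP-implicit) law's
#' `K'` unchanged at normoxic ATP, `K^AB` is chosen so that
#' `(K_M,ATP/[ATP]_normoxia + 1) * K^AB = K'`.
#'
#' @param k_prime Original substrate Michaelis constant `K'` (same
#'   concentration units as `k_m_atp` and `atp_normoxia` need not match
#'   `k_prime`; only `k_m_atp`/`atp_normoxia` must share units).
#' @param k_m_atp ATP dissociation constant of the kinase.
#' @param atp_normoxia Normoxic ATP concentration, same units as `k_m_atp`.
#' @return The calibrated `K^AB`, in the units of `k_prime`.
#' @export
calibrate_kab <- function(k_prime, k_m_atp, atp_normoxia) {
  stopifnot(all(k_prime > 0), all(k_m_atp > 0), all(atp_normoxia > 0))
  k_prime / (k_m_atp / atp_normoxia + 1)
}

#' ATP-dependent phosphorylation law
#'
#' Constructor for the ordered bi-substrate (ATP first, then protein)
#' phosphorylation rate law. `k_ab` may be supplied directly or calibrated
#' from `k_prime` via [calibrate_kab()].
#'
#' @param vmax Maximal rate.
#' @param k_m_atp ATP dissociation constant (default 100, nM scale in the
#'   shipped model tables the per-reaction values override this).
#' @param k_ab Protein dissociation constant from the ATP-enzyme complex.
#' @param k_prime Original ATP-implicit Michaelis constant, retained for
#'   provenance and used to derive `k_ab` when `k_ab` is `NULL`
#'   (`atp_normoxia` then required).
#' @param atp_normoxia Normoxic ATP used for calibration when deriving
#'   `k_ab`; same units as `k_m_atp`.
#' @param inhibitor_target Optional drug-target tag (see [drug_targets()]).
#' @return Object of class `phospho_law`.
#' @export
phospho_law <- function(vmax, k_m_atp = 100, k_ab = NULL, k_prime = NULL,
                        atp_normoxia = NULL, inhibitor_target = NULL) {
  stopifnot(vmax > 0, k_m_atp > 0)
  if (is.null(k_ab)) {
    if (is.null(k_prime) || is.null(atp_normoxia)) {
      stop("either k_ab, or k_prime plus atp_normoxia, must be supplied", call. = FALSE)
    }
    k_ab <- calibrate_kab(k_prime, k_m_atp, atp_normoxia)
  }
  stopifnot(k_ab > 0)
  structure(list(vmax = vmax, k_m_atp = k_m_atp, k_ab = k_ab,
                 k_prime = k_prime, inhibitor_target = inhibitor_target),
            class = "phospho_law")
}

#' Phosphorylation rate with explicit ATP dependence
#'
#' `V_max [ATP][P] / (K_M,ATP K^AB + K^AB [ATP] + [ATP][P])`. Bounded by
#' `vmax`, monotone increasing in both ATP and protein, and equal to the
#' original ATP-implicit law at the calibration ATP level.
#'
#' @param atp ATP concentration (> 0), same units as `law$k_m_atp`.
#' @param protein Protein substrate concentration (>= 0), same units as
#'   `law$k_ab`.
#' @param law A [phospho_law()].
#' @return Reaction rate.
#' @export
phospho_rate <- function(atp, protein, law) {
  phospho_rate_inhibited(atp, protein, d_over_ki = 0, law = law)
}

#' Phosphorylation rate under ATP-competitive inhibition
#'
#' The inhibitor enlarges only the `K_M,ATP K^AB` term by `(1 + [D]/K_i)`.
#' At `d_over_ki = 0` this is identical to [phospho_rate()]. As
#' `d_over_ki` grows the rate decreases monotonically towards the
#' drug-insensitive floor `V_max [ATP][P] / (K^AB [ATP] + [ATP][P])`
#' (the inhibitor competes with ATP, so saturating ATP-protein terms are
#' untouched); the rate reaches zero only in the regime where the
#' `K_M,ATP K^AB` term dominates the denominator.
#'
#' @inheritParams phospho_rate
#' @param d_over_ki Drug concentration in units of its inhibition constant,
#'   `[D]/K_i >= 0`.
#' @return Reaction rate.
#' @export
phospho_rate_inhibited <- function(atp, protein, d_over_ki, law) {
  if (any(atp <= 0)) stop("atp must be > 0", call. = FALSE)
  if (any(protein < 0)) stop("protein must be >= 0", call. = FALSE)
  if (any(d_over_ki < 0)) stop("d_over_ki must be >= 0", call. = FALSE)
  law$vmax * atp * protein /
    (law$k_m_atp * law$k_ab * (1 + d_over_ki) + law$k_ab * atp + atp * protein)
}

#' VEGF synthesis law driven by HIF-module mRNA
#'
#' @param k_syn_original Constant VEGF synthesis rate of the original
#'   (normoxia-only) tumor model.
#' @param k_alpha Dimensionless exponent amplifying mRNA changes (default 2,
#'   accounting for protein expression exceeding the mRNA change).
#' @param mrna0 Normoxic mRNA baseline (> 0), computed by equilibrating the
#'   HIF module at normoxia.
#' @return Object of class `vegf_synthesis_law`.
#' @export
vegf_synthesis_law <- function(k_syn_original, k_alpha = 2, mrna0) {
  stopifnot(k_syn_original > 0, k_alpha > 0, mrna0 > 0)
  structure(list(k_syn_original = k_syn_original, k_alpha = k_alpha, mrna0 = mrna0),
            class = "vegf_synthesis_law")
}

#' VEGF synthesis rate
#'
#' `k_syn(original) * (mRNA/mRNA0)^k_alpha`; returns `k_syn_original`
#' unchanged at the normoxic mRNA baseline.
#'
#' @param mrna Current mRNA concentration (>= 0).
#' @param law A [vegf_synthesis_law()].
#' @return Synthesis rate.
#' @export
vegf_synthesis_rate <- function(mrna, law) {
  if (any(mrna < 0)) stop("mrna must be >= 0", call. = FALSE)
  if (law$mrna0 <= 0) stop("mrna0 must be > 0", call. = FALSE)
  law$k_syn_original * (mrna / law$mrna0)^law$k_alpha
}

#' VEGF-receptor binding law
#'
#' @param k1f Association rate constant.
#' @param k1r Dissociation rate constant.
#' @return Object of class `vegf_binding_law`.
#' @export
vegf_binding_law <- function(k1f, k1r) {
  stopifnot(k1f >= 0, k1r >= 0)
  structure(list(k1f = k1f, k1r = k1r), class = "vegf_binding_law")
}

#' Net VEGF-receptor binding rate under binding inhibition
#'
#' `k_1f [VEGF][VEGFR] / (1 + [D]/K_i) - k_1r [VVEGFR]`: only the forward
#' (association) term is divided by the inhibition factor; dissociation of
#' pre-formed complex is unaffected.
#'
#' @param vegf,vegfr,vvegfr Concentrations (>= 0) of free ligand, free
#'   receptor and complex.
#' @param d_over_ki Inhibitor strength `[D]/K_i >= 0`.
#' @param law A [vegf_binding_law()].
#' @return Net binding rate (may be negative).
#' @export
vegf_binding_rate <- function(vegf, vegfr, vvegfr, d_over_ki, law) {
  if (any(c(vegf, vegfr, vvegfr) < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(d_over_ki < 0)) stop("d_over_ki must be >= 0", call. = FALSE)
  law$k1f * vegf * vegfr / (1 + d_over_ki) - law$k1r * vvegfr
}

#' Recognized drug-target tags
#'
#' The four drug actions the model supports: ATP-competitive inhibition of
#' RAF, MEK or Akt phosphorylation, and inhibition of VEGF binding to VEGFR.
#'
#' @return Character vector of target names.
#' @export
drug_targets <- function() {
  c("RAF_phospho", "MEK_phospho", "AKT_phospho", "VEGF_binding")
}
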