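#' Coupling configuration for model assembly
#'
#' Names the handles through which the HIF (hypoxia) module drives the tumor
#' signaling module and how the ATP-explicit phosphorylation laws are
#' calibrated.
#'
#' @param mrna_species Id of the HIF-module mRNA output species.
#' @param vegf_synthesis_reaction Id of the tumor-module VEGF synthesis
#'   reaction.
#' @param vegf_species Id of the VEGF protein species (its tabulated initial
#'   value is the original model's normoxic baseline).
#' @param vegf_degradation_reaction Id of the VEGF degradation reaction whose
#'   rate constant is re-derived so the normoxic VEGF baseline matches the
#'   original model.
#' @param k_alpha Amplification exponent of the mRNA ratio (default 2).
#' @param atp_params An [atp_model()].
#' @param k_m_atp_default Default ATP Michaelis constant (nM) for converted
#'   reactions that do not carry a per-reaction `k_m_atp`.
#' @param calibration_atp `"eq1_normoxia"` (default) calibrates `K^AB` at the
#'   ATP level the oxygen-ATP map returns at normoxia, which makes the
#'   integrated model's normoxic rates match the original model's exactly;
#'   `"parameter"` uses the literature `atp_normoxia` value instead (the two
#'   differ by about 3%, leaving a ~0.1% rate mismatch at normoxia).
#' @return Object of class `coupling_config`.
#' @export
coupling_config <- function(mrna_species = "mRNA",
                            vegf_synthesis_reaction = "t_vegf_syn",
                            vegf_species = "VEGF",
                            vegf_degradation_reaction = "t_vegf_deg",
                            k_alpha = 2,
                            atp_params = atp_model(),
                            k_m_atp_default = 100,
                            calibration_atp = c("eq1_normoxia", "parameter")) {
  stopifnot(k_alpha > 0)
  structure(list(mrna_species = mrna_species,
                 vegf_synthesis_reaction = vegf_synthesis_reaction,
                 vegf_species = vegf_species,
                 vegf_degradation_reaction = vegf_degradation_reaction,
                 k_alpha = k_alpha, atp_params = atp_params,
                 k_m_atp_default = k_m_atp_default,
                 calibration_atp = match.arg(calibration_atp),
                 mrna0 = NULL, kab_calibration = NULL),
            class = "coupling_config")
}

reaction_ids <- function(network) vapply(network$reactions, `[[`, "", "id")

#' Assemble the integrated hypoxia-tumor model
#'
#' Merges the HIF and tumor networks and applies the three coupling steps:
#' (a) the VEGF synthesis rate becomes `k_syn * (mRNA/mRNA0)^k_alpha`, with
#' `mRNA0` computed by equilibrating the HIF module alone at normoxia;
#' (b) every reaction tagged `atp_dependent` has its ATP-implicit law
#' replaced by the ATP-explicit law with `K^AB` calibrated so normoxic rates
#' are unchanged; (c) the VEGF degradation constant is set to
#' `k_syn / VEGF0` so the normoxic VEGF baseline equals the original
#' model's tabulated value (the assembled network conserves VEGF inside
#' binding complexes, so that ratio is the exact normoxic free-VEGF steady
#' state).
#'
#' @param hif `reaction_network` of the hypoxia (HIF) module.
#' @param tumor `reaction_network` of the tumor signaling module.
#' @param coupling A [coupling_config()].
#' @param settings [solver_settings()] used for the HIF-module equilibration.
#' @return The integrated `reaction_network`, with `coupling` (including the
#'   computed `mrna0` and the per-reaction `kab_calibration` records)
#'   attached.
#' @export
assemble_integrated_model <- function(hif, tumor, coupling = coupling_config(),
                                      settings = solver_settings()) {
  problems <- character(0)
  if (!(coupling$mrna_species %in% hif$species$id)) {
    problems <- c(problems, sprintf("HIF module lacks mRNA species '%s'",
                                    coupling$mrna_species))
  }
  if (!(coupling$vegf_synthesis_reaction %in% reaction_ids(tumor))) {
    problems <- c(problems, sprintf("tumor module lacks VEGF synthesis reaction '%s'",
                                    coupling$vegf_synthesis_reaction))
  }
  if (!(coupling$vegf_degradation_reaction %in% reaction_ids(tumor))) {
    problems <- c(problems, sprintf("tumor module lacks VEGF degradation reaction '%s'",
                                    coupling$vegf_degradation_reaction))
  }
  if (!(coupling$vegf_species %in% tumor$species$id)) {
    problems <- c(problems, sprintf("tumor module lacks VEGF species '%s'",
                                    coupling$vegf_species))
  }
  untagged <- vapply(tumor$reactions, function(r) {
    r$rate_law == "atp_phospho" && !isTRUE(r$atp_dependent)
  }, logical(1))
  if (any(untagged)) {
    problems <- c(problems,
                  paste("phosphorylation reactions not tagged atp_dependent:",
                        paste(vapply(tumor$reactions[untagged], `[[`, "", "id"),
                              collapse = ", ")))
  }
  if (length(problems)) {
    stop("cannot assemble integrated model:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  # normoxic mRNA baseline from the HIF module alone
  hif_ss <- integrate_to_steady_state(hif, initial_state(hif), cell_env(),
                                      settings)
  if (!hif_ss$converged) {
    stop("HIF module failed to equilibrate at normoxia", call. = FALSE)
  }
  mrna0 <- unname(hif_ss$state[coupling$mrna_species])
  if (!is.finite(mrna0) || mrna0 <= 0) {
    stop("normoxic mRNA baseline must be > 0 (got ", mrna0, ")", call. = FALSE)
  }

  shared <- intersect(hif$species$id, tumor$species$id)
  species <- rbind(hif$species, tumor$species[!(tumor$species$id %in% shared), ])
  rownames(species) <- NULL

  atp_cal_uM <- switch(coupling$calibration_atp,
                       eq1_normoxia = atp_level(1, coupling$atp_params),
                       parameter = coupling$atp_params$atp_normoxia)
  atp_cal_nM <- atp_cal_uM * 1000

  reactions <- c(hif$reactions, tumor$reactions)
  if (anyDuplicated(vapply(reactions, `[[`, "", "id"))) {
    stop("duplicate reaction ids across modules", call. = FALSE)
  }
  kab_records <- list()
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (r$id == coupling$vegf_synthesis_reaction) {
      r$params$mrna <- coupling$mrna_species
      r$params$mrna0 <- mrna0
      r$params$k_alpha <- coupling$k_alpha
    }
    if (r$id == coupling$vegf_degradation_reaction) {
      k_syn <- tumor$reactions[[match(coupling$vegf_synthesis_reaction,
                                      reaction_ids(tumor))]]$params$k_syn
      vegf0 <- tumor$species$initial_conc[tumor$species$id == coupling$vegf_species]
      if (vegf0 <= 0) stop("VEGF baseline must be > 0", call. = FALSE)
      r$params$k <- k_syn / vegf0
    }
    if (isTRUE(r$atp_dependent)) {
      if (r$rate_law != "atp_phospho") {
        stop(sprintf("reaction '%s' tagged atp_dependent but has law '%s'",
                     r$id, r$rate_law), call. = FALSE)
      }
      km <- if (!is.null(r$params$k_m_atp)) r$params$k_m_atp else coupling$k_m_atp_default
      r$params$k_m_atp <- km
      r$params$k_ab <- calibrate_kab(r$params$k_prime, km, atp_cal_nM)
      kab_records[[r$id]] <- list(k_prime = r$params$k_prime, k_m_atp = km,
                                  k_ab = r$params$k_ab)
    }
    reactions[[j]] <- r
  }

  coupling$mrna0 <- mrna0
  coupling$kab_calibration <- kab_records
  coupling$atp_calibration_nM <- atp_cal_nM
  net <- structure(list(species = species, reactions = reactions,
                        clamped = union(hif$clamped, tumor$clamped),
                        atp = coupling$atp_params, coupling = coupling),
                   class = "reaction_network")
  net$stoich <- stoichiometry_matrix(net)
  net
}

#' Load and assemble the shipped reconstructed model
#'
#' Convenience wrapper reading the packaged species/reaction tables (a
#' synthetic reconstruction of the published 189-species/86-reaction
#' integrated model; every row carries `provenance = reconstructed`) and
#' assembling them.
#'
#' @param settings [solver_settings()] for the HIF equilibration.
#' @return Assembled `reaction_network`.
#' @export
load_builtin_model <- function(settings = solver_settings()) {
  dir <- system.file("extdata", "model", package = "hypoxsig")
  hif <- load_model_tables(file.path(dir, "species_hif_synthetic.tsv"),
                           file.path(dir, "reactions_hif_synthetic.tsv"))
  tumor <- load_model_tables(file.path(dir, "species_tumor_synthetic.tsv"),
                             file.path(dir, "reactions_tumor_synthetic.tsv"),
                             clamped = character(0))
  assemble_integrated_model(hif, tumor, coupling_config(), settings)
}

#' Load the raw (unassembled) module networks of the shipped model
#'
#' @return List with elements `hif` and `tumor`, each a `reaction_network`
#'   still carrying the original (ATP-implicit, constant-VEGF-synthesis)
#'   rate laws.
#' @export
load_builtin_modules <- function() {
  dir <- system.file("extdata", "model", package = "hypoxsig")
  list(hif = load_model_tables(file.path(dir, "species_hif_synthetic.tsv"),
                               file.path(dir, "reactions_hif_synthetic.tsv")),
       tumor = load_model_tables(file.path(dir, "species_tumor_synthetic.tsv"),
                                 file.path(dir, "reactions_tumor_synthetic.tsv"),
                                 clamped = character(0)))
}
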