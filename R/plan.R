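#' Flatten a network into the compiled-evaluator plan
#'
#' Packs every reaction's law, parameters and species indices into integer
#' and double vectors consumed by the compiled right-hand side. Built once
#' per network and cached on first use by the integrator.
#'
#' @param network A `reaction_network`.
#' @return A list understood by the compiled evaluator.
#' @keywords internal
#' @export
network_plan <- function(network) {
  codes <- c(mass_action = 1L, degradation = 2L, michaelis_menten = 3L,
             atp_phospho = 4L, vegf_synthesis = 5L, vegf_binding = 6L)
  sp <- network$species$id
  idx <- function(ids) match(ids, sp)
  m <- length(network$reactions)
  law <- integer(m); drug_idx <- integer(m); enz_idx <- integer(m)
  par <- matrix(0, nrow = 6, ncol = m)
  r_idx <- integer(0); r_coef <- numeric(0); r_off <- integer(m + 1)
  p_idx <- integer(0); p_coef <- numeric(0); p_off <- integer(m + 1)
  r_off[1] <- 0L; p_off[1] <- 0L
  for (j in seq_len(m)) {
    r <- network$reactions[[j]]
    law[j] <- codes[[r$rate_law]]
    drug_idx[j] <- if (is.na(r$drug_target)) 0L else match(r$drug_target, drug_targets())
    p <- r$params
    g <- function(k, default = 0) if (!is.null(p[[k]])) p[[k]] else default
    switch(r$rate_law,
      mass_action = { par[1, j] <- p$kf; par[2, j] <- g("kr") },
      degradation = { par[1, j] <- p$k },
      michaelis_menten = {
        par[1, j] <- p$km; par[2, j] <- g("vmax"); par[3, j] <- g("kcat")
        if (!is.null(p$enzyme)) enz_idx[j] <- idx(p$enzyme)
      },
      atp_phospho = {
        par[1, j] <- p$k_prime; par[2, j] <- g("vmax"); par[3, j] <- g("kcat")
        par[4, j] <- g("k_ab"); par[5, j] <- g("k_m_atp", 100)
        if (!is.null(p$enzyme)) enz_idx[j] <- idx(p$enzyme)
      },
      vegf_synthesis = {
        par[1, j] <- p$k_syn; par[2, j] <- g("k_alpha", 2)
        par[3, j] <- g("mrna0")
        if (!is.null(p$mrna)) enz_idx[j] <- idx(p$mrna)
      },
      vegf_binding = { par[1, j] <- p$k1f; par[2, j] <- p$k1r })
    r_idx <- c(r_idx, idx(names(r$reactants))); r_coef <- c(r_coef, as.numeric(r$reactants))
    p_idx <- c(p_idx, idx(names(r$products))); p_coef <- c(p_coef, as.numeric(r$products))
    r_off[j + 1] <- length(r_idx); p_off[j + 1] <- length(p_idx)
  }
  list(law = law, par = par, drug_idx = drug_idx, enz_idx = enz_idx,
       r_off = r_off, r_idx = r_idx, r_coef = r_coef,
       p_off = p_off, p_idx = p_idx, p_coef = p_coef,
       clamped = match(network$clamped, sp))
}

#' Right-hand side via the compiled evaluator
#'
#' Same contract as [rhs()] but evaluated by the compiled path the
#' integrator uses. Exposed so the two evaluators can be compared directly.
#'
#' @inheritParams rhs
#' @param plan Optional pre-built [network_plan()].
#' @return Named numeric derivative vector.
#' @export
rhs_fast <- function(network, state, env = cell_env(), plan = NULL) {
  if (is.null(plan)) plan <- network_plan(network)
  atp_nM <- atp_level(env$o2_fraction, network$atp) * 1000
  dx <- rhs_compiled(plan, as.numeric(state), atp_nM, env$drugs, env$o2_fraction)
  stats::setNames(dx, network$species$id)
}
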