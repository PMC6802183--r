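#' @useDynLib hypoxsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RATE_LAWS <- c("mass_action", "michaelis_menten", "atp_phospho",
               "vegf_synthesis", "vegf_binding", "degradation")

#' External environment of the cell
#'
#' The model's two inputs: oxygen (as a fraction of normoxia) and the active
#' drug inhibitions, each expressed as `[D]/K_i`.
#'
#' @param o2_fraction Oxygen as fraction of normoxia, in (0, 1].
#' @param drugs Named numeric vector mapping a subset of [drug_targets()] to
#'   non-negative `[D]/K_i` values. Unnamed targets default to 0.
#' @return Object of class `cell_env`.
#' @export
cell_env <- function(o2_fraction = 1, drugs = numeric(0)) {
  stopifnot(is.numeric(o2_fraction), length(o2_fraction) == 1L,
            o2_fraction > 0, o2_fraction <= 1)
  d <- stats::setNames(numeric(4), drug_targets())
  if (length(drugs)) {
    if (is.null(names(drugs)) || !all(names(drugs) %in% drug_targets())) {
      stop("drugs must be named with targets among: ",
           paste(drug_targets(), collapse = ", "), call. = FALSE)
    }
    if (any(drugs < 0)) stop("[D]/K_i must be >= 0", call. = FALSE)
    d[names(drugs)] <- drugs
  }
  structure(list(o2_fraction = o2_fraction, drugs = d), class = "cell_env")
}

parse_side <- function(txt) {
  # "A + 2 B" -> c(A = 1, B = 2); empty string -> empty vector
  txt <- trimws(txt)
  if (is.na(txt) || txt == "") return(stats::setNames(integer(0), character(0)))
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  coefs <- integer(length(parts)); ids <- character(length(parts))
  for (i in seq_along(parts)) {
    m <- regmatches(parts[i], regexec("^([0-9]+)\\s+(\\S+)$", parts[i]))[[1]]
    if (length(m) == 3) {
      coefs[i] <- as.integer(m[2]); ids[i] <- m[3]
    } else {
      coefs[i] <- 1L; ids[i] <- parts[i]
    }
  }
  if (any(coefs <= 0)) stop("stoichiometric coefficients must be positive integers")
  out <- stats::setNames(integer(0), character(0))
  for (i in seq_along(ids)) { # merge duplicates
    if (ids[i] %in% names(out)) out[ids[i]] <- out[ids[i]] + coefs[i]
    else out[ids[i]] <- coefs[i]
  }
  out
}

parse_params <- function(txt) {
  txt <- trimws(txt)
  if (is.na(txt) || txt == "") return(list())
  parts <- trimws(strsplit(txt, "[;,]")[[1]])
  parts <- parts[parts != ""]
  out <- list()
  for (p in parts) {
    kv <- trimws(strsplit(p, "=", fixed = TRUE)[[1]])
    if (length(kv) != 2) stop("malformed param entry: '", p, "'")
    val <- suppressWarnings(as.numeric(kv[2]))
    out[[kv[1]]] <- if (is.na(val)) kv[2] else val
  }
  out
}

required_params <- function(law, params) {
  has <- function(k) !is.null(params[[k]])
  ok <- switch(law,
    mass_action      = has("kf"),
    degradation      = has("k"),
    michaelis_menten = has("km") && (has("vmax") || (has("kcat") && has("enzyme"))),
    atp_phospho      = has("k_prime") && (has("vmax") || (has("kcat") && has("enzyme"))),
    vegf_synthesis   = has("k_syn"),
    vegf_binding     = has("k1f") && has("k1r"),
    FALSE)
  ok
}

#' Load a reaction network from species and reaction tables
#'
#' Reads the tabular model definition (TSV/CSV with the columns documented
#' below) and returns a validated `reaction_network`. Species row order is
#' preserved as the state ordering.
#'
#' Species columns: `id`, `initial_conc`, `unit`, `module`,
#' `is_phospho_form`, `phospho_pair`, `provenance`. Reaction columns: `id`,
#' `reactants`, `products` (e.g. `"VEGF + VEGFR"`, coefficient as integer
#' prefix), `rate_law`, `params` (key=value list, `;` separated; species-id
#' valued entries such as `enzyme=pMEK` act as modifiers), `atp_dependent`,
#' `drug_target`, `provenance`.
#'
#' @param species_table Path to a delimited file, or a data.frame.
#' @param reaction_table Path to a delimited file, or a data.frame.
#' @param clamped Species ids whose value is set by the environment (their
#'   derivative is held at zero); the oxygen species of the shipped model.
#' @return Object of class `reaction_network`.
#' @export
load_model_tables <- function(species_table, reaction_table, clamped = "O2") {
  read_tab <- function(x) {
    if (is.data.frame(x)) return(x)
    sep <- if (grepl("\\.csv$", x)) "," else "\t"
    utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      quote = "", comment.char = "")
  }
  sp <- read_tab(species_table)
  rx <- read_tab(reaction_table)

  need_sp <- c("id", "initial_conc", "unit", "module", "is_phospho_form",
               "phospho_pair", "provenance")
  if (!all(need_sp %in% names(sp))) {
    stop("species table missing columns: ",
         paste(setdiff(need_sp, names(sp)), collapse = ", "), call. = FALSE)
  }
  need_rx <- c("id", "reactants", "products", "rate_law", "params",
               "atp_dependent", "drug_target", "provenance")
  if (!all(need_rx %in% names(rx))) {
    stop("reaction table missing columns: ",
         paste(setdiff(need_rx, names(rx)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sp$id)) stop("duplicate species ids", call. = FALSE)
  if (any(!is.finite(sp$initial_conc)) || any(sp$initial_conc < 0)) {
    stop("initial_conc must be finite and >= 0", call. = FALSE)
  }
  pair <- sp$phospho_pair
  bad_pair <- !is.na(pair) & pair != "" & !(pair %in% sp$id)
  if (any(bad_pair)) {
    stop("phospho_pair names unknown species: ",
         paste(unique(pair[bad_pair]), collapse = ", "), call. = FALSE)
  }

  reactions <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    row <- rx[i, ]
    law <- row$rate_law
    if (!(law %in% RATE_LAWS)) {
      stop(sprintf("row %d (reaction '%s'): unknown rate law '%s'",
                   i, row$id, law), call. = FALSE)
    }
    reac <- parse_side(row$reactants)
    prod <- parse_side(row$products)
    params <- parse_params(row$params)
    if (!required_params(law, params)) {
      stop(sprintf("row %d (reaction '%s'): incomplete params for law '%s'",
                   i, row$id, law), call. = FALSE)
    }
    refs <- c(names(reac), names(prod),
              unlist(params[names(params) %in% c("enzyme", "mrna")],
                     use.names = FALSE))
    missing_sp <- setdiff(refs, sp$id)
    if (length(missing_sp)) {
      stop(sprintf("row %d (reaction '%s'): unknown species: %s",
                   i, row$id, paste(missing_sp, collapse = ", ")), call. = FALSE)
    }
    tgt <- row$drug_target
    if (!is.na(tgt) && tgt != "" && !(tgt %in% drug_targets())) {
      stop(sprintf("row %d (reaction '%s'): unknown drug target '%s'",
                   i, row$id, tgt), call. = FALSE)
    }
    reactions[[i]] <- list(
      id = row$id, reactants = reac, products = prod, rate_law = law,
      params = params, atp_dependent = isTRUE(as.logical(row$atp_dependent)),
      drug_target = if (is.na(tgt) || tgt == "") NA_character_ else tgt,
      provenance = row$provenance)
  }
  if (anyDuplicated(vapply(reactions, `[[`, "", "id"))) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  net <- structure(list(species = sp, reactions = reactions,
                        clamped = intersect(clamped, sp$id),
                        atp = atp_model(), coupling = NULL),
                   class = "reaction_network")
  net$stoich <- stoichiometry_matrix(net)
  net
}

#' Stoichiometry matrix (species x reactions)
#'
#' Net integer stoichiometry; modifiers (params `enzyme`, `mrna`) and
#' catalytic species written on both sides contribute zero.
#'
#' @param network A `reaction_network`.
#' @return Integer matrix with species ids as rownames, reaction ids as
#'   colnames.
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species$id
  S <- matrix(0L, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`, "", "id")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    if (length(r$reactants)) {
      S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    }
    if (length(r$products)) {
      S[names(r$products), j] <- S[names(r$products), j] + r$products
    }
  }
  S
}

#' Number of rate parameters in a network
#'
#' Counts numeric entries of every reaction's parameter list (modifier
#' references excluded). When `distinct_kab` is TRUE, calibrated `k_ab`
#' values present after assembly are counted in addition to the `k_prime`
#' they were derived from; both counts are reported by the assembly summary.
#'
#' @param network A `reaction_network`.
#' @param distinct_kab Count derived `k_ab` values as separate parameters.
#' @return Integer.
#' @export
count_parameters <- function(network, distinct_kab = FALSE) {
  n <- 0L
  for (r in network$reactions) {
    p <- r$params
    num <- vapply(p, is.numeric, logical(1))
    if (!distinct_kab && !is.null(p$k_ab) && !is.null(p$k_prime)) {
      num[names(p) == "k_ab"] <- FALSE
    }
    n <- n + sum(num)
  }
  n
}

eval_one_rate <- function(r, conc, atp, drugs, mrna0_default = NULL) {
  p <- r$params
  d <- if (!is.na(r$drug_target)) drugs[[r$drug_target]] else 0
  switch(r$rate_law,
    mass_action = {
      fwd <- p$kf * prod(conc[names(r$reactants)]^r$reactants)
      rev <- if (!is.null(p$kr)) p$kr * prod(conc[names(r$products)]^r$products) else 0
      fwd - rev
    },
    degradation = p$k * conc[[names(r$reactants)[1]]],
    michaelis_menten = {
      s <- conc[[names(r$reactants)[1]]]
      vmax <- if (!is.null(p$vmax)) p$vmax else p$kcat * conc[[p$enzyme]]
      vmax * s / (p$km + s)
    },
    atp_phospho = {
      s <- conc[[names(r$reactants)[1]]]
      vmax <- if (!is.null(p$vmax)) p$vmax else p$kcat * conc[[p$enzyme]]
      if (is.null(p$k_ab)) {
        # original, ATP-implicit law; drug term enlarges K' analogously
        vmax * s / (p$k_prime * (1 + d) + s)
      } else {
        km_atp <- if (!is.null(p$k_m_atp)) p$k_m_atp else 100
        vmax * atp * s / (km_atp * p$k_ab * (1 + d) + p$k_ab * atp + atp * s)
      }
    },
    vegf_synthesis = {
      if (is.null(p$mrna) || is.null(p$mrna0)) {
        p$k_syn
      } else {
        ka <- if (!is.null(p$k_alpha)) p$k_alpha else 2
        p$k_syn * (conc[[p$mrna]] / p$mrna0)^ka
      }
    },
    vegf_binding = {
      v <- conc[[names(r$reactants)[1]]]
      rr <- conc[[names(r$reactants)[2]]]
      c1 <- conc[[names(r$products)[1]]]
      p$k1f * v * rr / (1 + d) - p$k1r * c1
    },
    stop("unknown rate law"))
}

#' Reaction rate vector (reference evaluator)
#'
#' Evaluates every reaction's rate law at the given state and environment,
#' with ATP set algebraically from the oxygen level ([atp_level()], converted
#' from micromolar to the network's nanomolar concentration scale) and
#' clamped species overridden from the environment. This is the plain-R
#' reference path; the integrator uses the compiled evaluator, and the two
#' are asserted equal in the test suite.
#'
#' @param network A `reaction_network`.
#' @param state Named or unnamed numeric vector in species order.
#' @param env A [cell_env()].
#' @return Numeric vector of rates, one per reaction.
#' @export
reaction_rates <- function(network, state, env = cell_env()) {
  conc <- prepare_state(network, state, env)
  atp_nM <- atp_level(env$o2_fraction, network$atp) * 1000
  vapply(network$reactions, eval_one_rate, numeric(1),
         conc = conc, atp = atp_nM, drugs = env$drugs)
}

prepare_state <- function(network, state, env, clamp_floor = 1e-8) {
  if (length(state) != nrow(network$species)) {
    stop("state length must equal species count", call. = FALSE)
  }
  if (any(!is.finite(state))) {
    bad <- network$species$id[!is.finite(state)]
    stop("non-finite state entries: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  conc <- stats::setNames(as.numeric(state), network$species$id)
  neg <- conc < 0
  if (any(conc < -10 * clamp_floor)) {
    bad <- network$species$id[conc < -10 * clamp_floor]
    stop("negative concentrations beyond solver round-off: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conc[neg] <- 0
  if (length(network$clamped)) conc[network$clamped] <- env$o2_fraction
  conc
}

#' Right-hand side of the network ODE (reference evaluator)
#'
#' Derivative = stoichiometry %*% rates. Clamped species have derivative
#' zero. Small negative state entries (stiff-solver round-off, within ten
#' times the absolute tolerance) are clamped to zero before rate evaluation;
#' larger negatives raise an error naming the species.
#'
#' @inheritParams reaction_rates
#' @return Numeric vector of derivatives in species order.
#' @export
rhs <- function(network, state, env = cell_env()) {
  v <- reaction_rates(network, state, env)
  dx <- as.numeric(network$stoich %*% v)
  names(dx) <- network$species$id
  if (length(network$clamped)) dx[network$clamped] <- 0
  dx
}

#' Right-hand side by per-reaction accumulation
#'
#' Same contract as [rhs()], but accumulates each reaction's contribution
#' directly instead of multiplying by the stoichiometry matrix. Used as the
#' stoichiometric-consistency oracle.
#'
#' @inheritParams reaction_rates
#' @return Numeric vector of derivatives in species order.
#' @export
rhs_accumulate <- function(network, state, env = cell_env()) {
  v <- reaction_rates(network, state, env)
  dx <- stats::setNames(numeric(nrow(network$species)), network$species$id)
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    if (length(r$reactants)) {
      dx[names(r$reactants)] <- dx[names(r$reactants)] - r$reactants * v[j]
    }
    if (length(r$products)) {
      dx[names(r$products)] <- dx[names(r$products)] + r$products * v[j]
    }
  }
  if (length(network$clamped)) dx[network$clamped] <- 0
  dx
}

#' Conserved moiety totals
#'
#' Returns a basis for the left null space of the stoichiometry matrix
#' restricted to interconversion reactions (synthesis and degradation
#' reactions — any reaction with an empty reactant or product side, or the
#' `degradation`/`vegf_synthesis` laws — are excluded, as are clamped
#' species). Each returned combination is constant along any trajectory in
#' which only the interconversion reactions fire.
#'
#' @param network A `reaction_network`.
#' @param tol Singular-value tolerance for the rank decision.
#' @return A list of named numeric vectors (possibly empty); each vector's
#'   names are species ids and the dot product with the state is conserved.
#' @export
moiety_conservation_totals <- function(network, tol = 1e-10) {
  open <- vapply(network$reactions, function(r) {
    r$rate_law %in% c("degradation", "vegf_synthesis") ||
      length(r$reactants) == 0 || length(r$products) == 0
  }, logical(1))
  keep_sp <- !(network$species$id %in% network$clamped)
  S <- network$stoich[keep_sp, !open, drop = FALSE]
  if (ncol(S) == 0 || nrow(S) == 0) return(list())
  sv <- svd(S, nu = nrow(S), nv = 0)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  if (rank >= nrow(S)) return(list())
  basis <- sv$u[, (rank + 1):nrow(S), drop = FALSE]
  rownames(basis) <- network$species$id[keep_sp]
  lapply(seq_len(ncol(basis)), function(k) {
    v <- basis[, k]
    v[abs(v) < 1e-12] <- 0
    v[v != 0]
  })
}

#' Initial state vector of a network
#'
#' @param network A `reaction_network`.
#' @return Named numeric vector in species order.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$initial_conc, network$species$id)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction_network: %d species, %d reactions, %d parameters\n",
              nrow(x$species), length(x$reactions), count_parameters(x)))
  if (!is.null(x$coupling)) {
    cat(sprintf("  assembled (mRNA0 = %.6g; %d ATP-converted reactions)\n",
                x$coupling$mrna0, length(x$coupling$kab_calibration)))
  }
  invisible(x)
}
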