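# Statistical AMPAR tetramer model: membrane-bound GluR1/GluR2 subunit
# counts are mapped to expected numbers of tetramer classes and to the total
# maximal synaptic conductance. Two tetramer-formation rules are supported:
# fully random draws of four subunits, and random dimerisation followed by
# pairing of like dimers (which forbids 1:3 and 3:1 heterotetramers).

#' Membrane receptor state
#'
#' @param n1 membrane-bound GluR1 subunits (particle units, real-valued).
#' @param n2 membrane-bound GluR2 subunits.
#' @param n1_phos membrane-bound S831-phosphorylated GluR1 subunits
#'   (a subset of \code{n1}: includes doubly phosphorylated subunits).
#' @return object of class \code{membrane_receptor_state}.
#' @export
membrane_receptor_state <- function(n1, n2, n1_phos = 0) {
  stopifnot(n1 >= 0, n2 >= 0, n1_phos >= 0)
  if (n1_phos > n1 + 1e-9) stop("n1_phos cannot exceed n1")
  structure(list(n1 = n1, n2 = n2, n1_phos = min(n1_phos, n1)),
            class = "membrane_receptor_state")
}

#' Single-channel conductance parameters
#'
#' Experimentally measured single-channel conductances of the four tetramer
#' classes: non-phosphorylated GluR1 homomers 12.4 pS, S831-phosphorylated
#' GluR1 homomers 18.9 pS, GluR2 homomers 2.2 pS, heteromers 2.5 pS.
#'
#' @param g_hom1_nonphos,g_hom1_phos,g_hom2,g_het conductances in pS.
#' @export
conductance_params <- function(g_hom1_nonphos = 12.4, g_hom1_phos = 18.9,
                               g_hom2 = 2.2, g_het = 2.5) {
  stopifnot(g_hom1_nonphos > 0, g_hom1_phos > 0, g_hom2 > 0, g_het > 0)
  structure(list(g_hom1_nonphos = g_hom1_nonphos,
                 g_hom1_phos = g_hom1_phos,
                 g_hom2 = g_hom2, g_het = g_het),
            class = "conductance_params")
}

#' Tetramer class probabilities under the random-assembly rule
#'
#' With N1 GluR1 subunits (N1p of them S831-phosphorylated) and N2 GluR2
#' subunits at the membrane, the probability that a tetramer is a
#' non-phosphorylated GluR1 homomer is approximately
#' \eqn{(N_1 - N_{1p})^4 / (N_1 + N_2)^4}, a phosphorylated GluR1 homomer
#' \eqn{(N_1^4 - (N_1 - N_{1p})^4) / (N_1 + N_2)^4}, a GluR2 homomer
#' \eqn{N_2^4 / (N_1 + N_2)^4}, and a heteromer the complement. The power
#' form approximates sampling without replacement and becomes exact as
#' N1 + N2 grows.
#'
#' @param state a \code{membrane_receptor_state}.
#' @return named vector (p_hom1_nonphos, p_hom1_phos, p_hom2, p_het); all
#'   zero when the membrane is empty.
#' @export
tetramer_probabilities_random <- function(state) {
  n1 <- state$n1; n2 <- state$n2; np <- state$n1_phos
  tot <- n1 + n2
  if (tot <= 0)
    return(c(p_hom1_nonphos = 0, p_hom1_phos = 0, p_hom2 = 0, p_het = 0))
  q1 <- n1 / tot; q1n <- (n1 - np) / tot; q2 <- n2 / tot
  p_hom1_nonphos <- q1n^4
  p_hom1_phos <- q1^4 - q1n^4
  p_hom2 <- q2^4
  p_het <- 1 - q1^4 - q2^4
  c(p_hom1_nonphos = p_hom1_nonphos, p_hom1_phos = p_hom1_phos,
    p_hom2 = p_hom2, p_het = p_het)
}

#' Tetramer class probabilities under the dimer-of-like-dimers rule
#'
#' Subunits first dimerise at random (fractions q^2, 2q(1-q), (1-q)^2 for
#' R1-R1, R1-R2, R2-R2 dimers, q = GluR1 fraction); tetramers then form only
#' from pairs of like dimers, renormalised over the three like-pair events.
#' Heterotetramers are therefore always 2:2, and no 1:3 or 3:1 composition
#' can occur. The S831-phosphorylated homomer share is computed from the
#' phosphorylated fraction of the GluR1 pool as in the random rule.
#'
#' @param state a \code{membrane_receptor_state}.
#' @param glur1_fraction_override optional q replacing n1/(n1+n2).
#' @return named probability vector as in
#'   \code{\link{tetramer_probabilities_random}}.
#' @export
tetramer_probabilities_dimer <- function(state, glur1_fraction_override = NULL) {
  n1 <- state$n1; n2 <- state$n2; np <- state$n1_phos
  tot <- n1 + n2
  if (tot <= 0)
    return(c(p_hom1_nonphos = 0, p_hom1_phos = 0, p_hom2 = 0, p_het = 0))
  q <- if (!is.null(glur1_fraction_override)) glur1_fraction_override
       else n1 / tot
  d11 <- q^2; d12 <- 2 * q * (1 - q); d22 <- (1 - q)^2
  tot_pairs <- d11^2 + d12^2 + d22^2
  p_hom1 <- d11^2 / tot_pairs
  p_het <- d12^2 / tot_pairs
  p_hom2 <- d22^2 / tot_pairs
  phi_nonphos <- if (n1 > 0) ((n1 - np) / n1)^4 else 1
  c(p_hom1_nonphos = p_hom1 * phi_nonphos,
    p_hom1_phos = p_hom1 * (1 - phi_nonphos),
    p_hom2 = p_hom2, p_het = p_het)
}

#' Total maximal synaptic conductance
#'
#' The expected tetramer count is (N1 + N2)/4 (real-valued by default,
#' ignoring unpaired subunits; floored when \code{floor_count = TRUE}); the
#' conductance is the probability-weighted sum of class counts times
#' single-channel conductances.
#'
#' @param state a \code{membrane_receptor_state}.
#' @param params a \code{conductance_params}.
#' @param rule \code{"random"} or \code{"dimer"}.
#' @param floor_count use the floored tetramer count.
#' @return conductance in pS.
#' @export
gsyn <- function(state, params = conductance_params(), rule = "random",
                 floor_count = FALSE) {
  p <- switch(rule,
              random = tetramer_probabilities_random(state),
              dimer = tetramer_probabilities_dimer(state),
              stop("unknown tetramer rule: ", rule))
  n_tet <- (state$n1 + state$n2) / 4
  if (floor_count) n_tet <- floor(n_tet)
  n_tet * sum(p * c(params$g_hom1_nonphos, params$g_hom1_phos,
                    params$g_hom2, params$g_het))
}

# Species pools entering the conductance model. Membrane-bound subunits
# include enzyme-bound membrane receptors (the subunit stays in the
# membrane while the kinase or phosphatase is attached).
glur_membrane_pools <- function(network) {
  sp <- network$species$name
  m1 <- grep("^GluR1_memb", sp, value = TRUE)
  m2 <- grep("^GluR2_memb", sp, value = TRUE)
  list(glur1 = m1,
       glur1_phos = grep("_S831", m1, value = TRUE),
       glur2 = m2)
}

#' Membrane receptor state from a concentration state vector
#'
#' Sums all membrane-bound GluR1/GluR2 species (including enzyme-bound
#' states) and converts concentrations to subunit counts. S831-carrying
#' membrane GluR1 species (singly and doubly phosphorylated) form the
#' phosphorylated pool.
#'
#' @param state named concentration vector (nM).
#' @param network the \code{reaction_network} defining the species pools.
#' @return a \code{membrane_receptor_state}.
#' @export
receptor_state_from_concentrations <- function(state, network) {
  pools <- glur_membrane_pools(network)
  cnt <- function(nms) concentration_to_subunit_count(
    sum(state[nms]), network$volume)
  membrane_receptor_state(cnt(pools$glur1), cnt(pools$glur2),
                          cnt(pools$glur1_phos))
}

#' Synaptic conductance from a concentration state
#'
#' @inheritParams receptor_state_from_concentrations
#' @param params a \code{conductance_params}.
#' @param rule tetramer rule.
#' @return conductance in pS.
#' @export
gsyn_from_state <- function(state, network, params = conductance_params(),
                            rule = "random") {
  gsyn(receptor_state_from_concentrations(state, network), params, rule)
}

#' Fraction of GluR2 carrying S880 phosphorylation
#'
#' @param state named concentration vector (nM).
#' @param network the network.
#' @return fraction in [0, 1] of all GluR2 subunits whose state includes
#'   S880 phosphorylation (membrane, internal, and phosphatase-bound).
#' @export
s880_fraction <- function(state, network) {
  sp <- network$species$name
  all2 <- grep("^GluR2", sp, value = TRUE)
  phos <- grep("^GluR2.*_S880", sp, value = TRUE)
  tot <- sum(state[all2])
  if (tot <= 0) return(0)
  sum(state[phos]) / tot
}

#' Tabulate conductance over a grid of subunit counts
#'
#' @param n1,n2,n1_phos vectors of counts; the full grid is evaluated
#'   (rows with n1_phos > n1 are dropped).
#' @param params a \code{conductance_params}.
#' @param rule tetramer rule.
#' @return data.frame with the grid and the conductance in pS.
#' @export
gsyn_table <- function(n1, n2, n1_phos = 0, params = conductance_params(),
                       rule = "random") {
  grid <- expand.grid(n1 = n1, n2 = n2, n1_phos = n1_phos)
  grid <- grid[grid$n1_phos <= grid$n1, , drop = FALSE]
  grid$gsyn <- vapply(seq_len(nrow(grid)), function(i)
    gsyn(membrane_receptor_state(grid$n1[i], grid$n2[i], grid$n1_phos[i]),
         params, rule), numeric(1))
  rownames(grid) <- NULL
  grid
}
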