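# Closed molecular families of the spine network. Each family is a weight
# vector w over species such that w' * (net stoichiometry) = 0 for every
# reaction: the weighted total is invariant under the full reaction set.
# Families tagged input = TRUE receive external flux during stimulation and
# are only conserved in unstimulated runs.

#' Conserved molecular families
#'
#' Returns the weight vectors of all closed families of the network (total
#' receptor, G-protein subunits, kinases, phosphatases, buffers, adenine
#' nucleotides, GluR subunits, ...). \code{Complex}/\code{pComplex} carry
#' weight 2 for CaMKII and CaM (they pair two subunits), and the PKA
#' holoenzyme carries two catalytic subunits and four cAMP-binding sites.
#'
#' @param network a \code{reaction_network}.
#' @return named list; each element is a named numeric weight vector with an
#'   attribute \code{input} indicating whether the family is fed by an
#'   external input channel.
#' @export
conserved_families <- function(network) {
  sp <- network$species$name
  # Families are defined over the shipped species inventory; a family whose
  # species are absent (reduced or toy models) is dropped rather than
  # checked partially.
  w <- function(..., input = FALSE) {
    v <- c(...)
    if (length(setdiff(names(v), sp))) return(NULL)
    attr(v, "input") <- input
    v
  }
  ones <- function(names, input = FALSE)
    w(stats::setNames(rep(1, length(names)), names), input = input)

  pkac_receptor <- c("PKAcR", "PKAcpR", "PKAcppR", "PKAcpppR",
                     "PKAcLR", "PKAcpLR", "PKAcppLR", "PKAcpppLR")
  lr_forms <- c("LR", "pLR", "ppLR", "pppLR", "ppppLR")
  r_forms <- c("R", "pR", "ppR", "pppR", "ppppR")
  ac1_cam <- c("AC1GsaGTPCaMCa4", "AC1CaMCa4", "AC1GiaGTPCaMCa4",
               "AC1GsaGTPCaMCa4ATP", "AC1CaMCa4ATP", "AC1GiaGTPCaMCa4ATP")
  glur1_ck <- c("GluR1_memb_CKCaMCa4", "GluR1_memb_S845_CKCaMCa4",
                "GluR1_memb_CKpCaMCa4", "GluR1_memb_S845_CKpCaMCa4")
  glur1_pp2b <- c("GluR1_memb_S845_PP2B", "GluR1_memb_S845_S831_PP2B",
                  "GluR1_S845_PP2B", "GluR1_S845_S831_PP2B")

  list(
    pmca = ones(c("PMCA", "PMCACa")),
    ncx = ones(c("NCX", "NCXCa")),
    leak = ones(c("Leak", "CaOutLeak")),
    calbindin = ones(c("Calbin", "CalbinC")),
    fixed_buffer = ones(c("fixedbuffer", "fixedbufferCa")),
    beta_receptor = ones(c(r_forms, lr_forms, pkac_receptor,
                           "LRGs", "GsR", "LRGsbg",
                           "ppppLRGi", "ppppLRGibg", "ppppRGi", "ppppRGibg")),
    gs_alpha = ones(c("Gs", "GsR", "LRGs", "GsaGTP", "GsaGDP",
                      "AC1GsaGTP", "AC1GsaGTPCaMCa4", "AC1GsaGTPCaMCa4ATP")),
    gs_betagamma = ones(c("Gs", "GsR", "LRGs", "LRGsbg", "Gsbg")),
    gi_alpha = ones(c("Gi", "ppppLRGi", "ppppRGi", "GiaGTP", "GiaGDP",
                      "AC1GiaGTPCaMCa4", "AC1GiaGTPCaMCa4ATP")),
    gi_betagamma = ones(c("Gi", "ppppLRGi", "ppppRGi",
                          "ppppLRGibg", "ppppRGibg", "Gibg")),
    gq_alpha = ones(c("Gqabg", "mGluR_Gqabg_Glu", "AChM1RGq", "M1RGq",
                      "GqaGTP", "GqaGDP", "PLCGqaGTP", "PLCCaGqaGTP",
                      "PLCCaGqaGTPPip2", "PLCCaGqaGTPDAG")),
    ac1 = ones(c("AC1", "AC1GsaGTP", ac1_cam)),
    ac8 = ones(c("AC8", "AC8CaMCa4", "AC8CaMCa4ATP")),
    calmodulin = w(stats::setNames(
      c(rep(1, 13), 2, 2, rep(1, 6 + 2 + 4 + 4 + 4)),
      c("CaM", "CaMCa2", "CaMCa3", "CaMCa4", "NgCaM",
        "PP2BCaM", "PP2BCaMCa2", "PP2BCaMCa3", "PP2BCaMCa4",
        "CKCaMCa4", "CKpCaMCa4", "CKpCaMCa4PP1",
        "PDE1CaMCa4", "Complex", "pComplex",
        ac1_cam, "AC8CaMCa4", "AC8CaMCa4ATP",
        "PDE1CaMCa4cAMP", "Ip35PP2BCaMCa4", "Ip35PP1PP2BCaMCa4",
        "PP1PP2BCaMCa4", glur1_ck, glur1_pp2b))),
    neurogranin = ones(c("Ng", "NgCaM")),
    pp2b = ones(c("PP2B", "PP2BCaM", "PP2BCaMCa2", "PP2BCaMCa3",
                  "PP2BCaMCa4", "Ip35PP2BCaMCa4", "Ip35PP1PP2BCaMCa4",
                  "PP1PP2BCaMCa4", glur1_pp2b)),
    camkii = w(stats::setNames(
      c(rep(1, 6), 2, 2, rep(1, 4)),
      c("CK", "CKCaMCa4", "CKpCaMCa4", "CKp", "CKpPP1", "CKpCaMCa4PP1",
        "Complex", "pComplex", glur1_ck))),
    pka_regulatory = ones(c("PKA", "PKAcAMP4", "PKAr")),
    pka_catalytic = w(stats::setNames(
      c(2, 2, rep(1, 1 + 8 + 5)),
      c("PKA", "PKAcAMP4", "PKAc", pkac_receptor,
        "I1PKAc", "PKAcPDE4", "PKAcPDE4cAMP",
        "GluR1_PKAc", "GluR1_S831_PKAc"))),
    epac1 = ones(c("Epac1", "Epac1cAMP")),
    inhibitor1 = ones(c("I1", "I1PKAc", "Ip35", "Ip35PP1",
                        "Ip35PP2BCaMCa4", "Ip35PP1PP2BCaMCa4")),
    pp1 = ones(c("PP1", "Ip35PP1", "Ip35PP1PP2BCaMCa4", "PP1PP2BCaMCa4",
                 "CKpPP1", "CKpCaMCa4PP1",
                 "GluR1_memb_S845_PP1", "GluR1_memb_S845_S831_PP1",
                 "GluR1_memb_S831_PP1B", "GluR1_memb_S845_S831_PP1B",
                 "GluR1_S845_PP1", "GluR1_S845_S831_PP1",
                 "GluR1_S831_PP1B", "GluR1_S845_S831_PP1B")),
    pde1 = ones(c("PDE1", "PDE1CaMCa4", "PDE1CaMCa4cAMP")),
    pde4 = ones(c("PDE4", "PDE4cAMP", "PKAcPDE4", "PKAcPDE4cAMP",
                  "pPDE4", "pPDE4cAMP")),
    adenine = w(stats::setNames(
      c(rep(1, 12), 4, 4),
      c("ATP", "cAMP", "AMP",
        "AC1GsaGTPCaMCa4ATP", "AC1CaMCa4ATP", "AC1GiaGTPCaMCa4ATP",
        "AC8CaMCa4ATP", "PDE1CaMCa4cAMP", "PDE4cAMP", "PKAcPDE4cAMP",
        "pPDE4cAMP", "Epac1cAMP", "PKAcAMP4", "PKAr"))),
    plc = ones(c("PLC", "PLCCa", "PLCGqaGTP", "PLCCaGqaGTP", "PLCCaPip2",
                 "PLCCaDAG", "PLCCaGqaGTPPip2", "PLCCaGqaGTPDAG")),
    pi_kinase = ones(c("PIkinase", "Ip3degPIk")),
    mglur = ones(c("mGluR", "mGluR_Glu", "mGluR_Glu_desens",
                   "mGluR_Gqabg_Glu"), input = TRUE),
    m1r = ones(c("M1R", "AChM1R", "AChM1RGq", "M1RGq"), input = TRUE),
    dgl = ones(c("DGL", "CaDGL", "DAGCaDGL")),
    dagk = ones(c("DAGK", "DAGKdag")),
    pkc = ones(c("PKC", "PKCCa", "PKCt", "PKCp",
                 "GluR1_memb_PKCt", "GluR1_memb_S845_PKCt",
                 "GluR1_memb_PKCp", "GluR1_memb_S845_PKCp",
                 "GluR2_memb_PKCt", "GluR2_memb_PKCp")),
    pla2 = ones(c("PLA2", "CaPLA2", "CaPLA2Pip2")),
    glur1 = ones(grep("^GluR1", sp, value = TRUE)),
    glur2 = ones(grep("^GluR2", sp, value = TRUE)),
    pp2a = ones(c("PP2A", "GluR2_S880_PP2A")),
    beta_ligand = ones(c("L", "LOut", lr_forms,
                         "PKAcLR", "PKAcpLR", "PKAcppLR", "PKAcpppLR",
                         "LRGs", "LRGsbg", "ppppLRGi", "ppppLRGibg"),
                       input = TRUE),
    glutamate = ones(c("Glu", "GluOut", "mGluR_Glu", "mGluR_Glu_desens",
                       "mGluR_Gqabg_Glu"), input = TRUE)
  )
}

net_stoichiometry <- function(network) {
  sp <- network$species$name
  ns <- length(sp)
  rx <- network$reactions
  S <- matrix(0, ns, nrow(rx), dimnames = list(sp, rx$id))
  for (i in seq_len(nrow(rx))) {
    re <- parse_side(rx$reactants[i])
    pr <- parse_side(rx$products[i])
    if (length(re)) S[names(re), i] <- S[names(re), i] - re
    if (length(pr)) S[names(pr), i] <- S[names(pr), i] + pr
  }
  S
}

check_conservation_symbolic <- function(network, families = conserved_families(network)) {
  S <- net_stoichiometry(network)
  for (nm in names(families)) {
    fam <- families[[nm]]
    wv <- stats::setNames(numeric(nrow(S)), rownames(S))
    wv[names(fam)] <- fam
    resid <- as.vector(wv %*% S)
    bad <- which(abs(resid) > 1e-12)
    if (length(bad))
      stop("family '", nm, "' is not conserved by reaction ",
           colnames(S)[bad[1]], " (net change ", resid[bad[1]], ")")
  }
  invisible(TRUE)
}

#' Conservation drift along a trajectory
#'
#' Relative peak-to-peak variation of every closed family total along a
#' simulated trajectory. Families fed by an input channel are skipped when
#' \code{stimulated = TRUE}.
#'
#' @param trajectory a \code{trajectory_result}.
#' @param network the network that produced it.
#' @param stimulated whether external input was applied during the run.
#' @return named numeric vector of relative drifts.
#' @export
conservation_drift <- function(trajectory, network, stimulated = TRUE) {
  fams <- conserved_families(network)
  conc <- trajectory$concentrations
  out <- c()
  for (nm in names(fams)) {
    fam <- fams[[nm]]
    if (stimulated && isTRUE(attr(fam, "input"))) next
    tot <- as.vector(conc[, names(fam), drop = FALSE] %*% fam)
    scale <- max(abs(tot[1]), 1e-9)
    out[nm] <- (max(tot) - min(tot)) / scale
  }
  out
}
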