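# Pathway-level concentration scalers. Each factor rescales the initial
# concentrations of the proteins upstream of one pathway; the GluR1 ratio
# redistributes the fixed 540 nM total of AMPA-receptor subunits between the
# GluR1 and GluR2 families while preserving each family's internal
# membrane/internal split.

SCALER_TARGETS <- list(
  f_pka = c("R", "Gs", "AC1", "AC8"),
  f_pkc = c("mGluR", "M1R", "Gqabg", "PLC"),
  f_camkii = c("CaM", "CK"),
  f_pp = c("PP1", "PP2B"),
  f_pde = c("PDE1", "PDE4"),
  ncx_scale = "NCX",
  pka_scale = "PKA",
  pkc_scale = "PKC"
)

#' Concentration scalers
#'
#' Bundle of multiplicative factors for the initial concentrations of the
#' pathway proteins, plus the GluR1 ratio
#' \eqn{[GluR1]_{tot} / ([GluR1]_{tot} + [GluR2]_{tot})}. All factors
#' default to 1 (and the GluR1 ratio to the value implied by the default
#' initial concentrations), under which \code{apply_scalers} is the
#' identity.
#'
#' @param glur1_ratio fraction of GluR subunits that are GluR1, in [0, 1].
#' @param f_pka,f_pkc,f_camkii,f_pp,f_pde pathway factors in [0, 2].
#' @param ncx_scale,pka_scale,pkc_scale single-protein factors in [0, 2].
#' @return object of class \code{concentration_scalers}.
#' @export
concentration_scalers <- function(glur1_ratio = 0.5, f_pka = 1, f_pkc = 1,
                                  f_camkii = 1, f_pp = 1, f_pde = 1,
                                  ncx_scale = 1, pka_scale = 1,
                                  pkc_scale = 1) {
  s <- list(glur1_ratio = glur1_ratio, f_pka = f_pka, f_pkc = f_pkc,
            f_camkii = f_camkii, f_pp = f_pp, f_pde = f_pde,
            ncx_scale = ncx_scale, pka_scale = pka_scale,
            pkc_scale = pkc_scale)
  if (s$glur1_ratio < 0 || s$glur1_ratio > 1)
    stop("glur1_ratio must be in [0, 1]")
  for (nm in setdiff(names(s), "glur1_ratio")) {
    if (s[[nm]] < 0 || s[[nm]] > 2)
      stop(nm, " must be in [0, 2]")
  }
  structure(s, class = "concentration_scalers")
}

#' Apply concentration scalers to a network
#'
#' Returns a new network whose initial concentrations are rescaled. The
#' GluR1 ratio reallocates the total GluR subunit concentration (540 nM by
#' default) between the GluR1 family and the GluR2 family; within each
#' family the split among states is preserved proportionally.
#'
#' @param network a \code{reaction_network}.
#' @param scalers a \code{concentration_scalers}.
#' @return a modified \code{reaction_network}.
#' @export
apply_scalers <- function(network, scalers) {
  stopifnot(inherits(scalers, "concentration_scalers"))
  net <- network
  init <- stats::setNames(net$species$init, net$species$name)
  for (nm in names(SCALER_TARGETS)) {
    targets <- SCALER_TARGETS[[nm]]
    init[targets] <- init[targets] * scalers[[nm]]
  }
  g1 <- grep("^GluR1", names(init), value = TRUE)
  g2 <- grep("^GluR2", names(init), value = TRUE)
  tot1 <- sum(init[g1]); tot2 <- sum(init[g2]); tot <- tot1 + tot2
  if (tot > 0) {
    new1 <- tot * scalers$glur1_ratio
    new2 <- tot * (1 - scalers$glur1_ratio)
    init[g1] <- if (tot1 > 0) init[g1] * new1 / tot1 else {
      # degenerate family: place the mass on the canonical internal state
      v <- init[g1]; v["GluR1"] <- new1; v
    }
    init[g2] <- if (tot2 > 0) init[g2] * new2 / tot2 else {
      v <- init[g2]; v["GluR2"] <- new2; v
    }
  }
  net$species$init <- unname(init[net$species$name])
  net$metadata$scalers <- unclass(scalers)
  net
}
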