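# Named experimental manipulations: pathway blockades, input-channel blocks,
# phosphorylation-site-deficient receptor variants, subunit knockouts.
# Reaction ids refer to the base (grouped) numbering of the packaged table;
# disabling a base id removes every expanded member.

MANIPULATION_PRESETS <- list(
  no_ca = list(kind = "zero_flux_channel", target = "Ca"),
  no_beta = list(kind = "zero_flux_channel", target = "L"),
  no_ach = list(kind = "zero_flux_channel", target = "ACh"),
  no_mglur = list(kind = "disable_reactions", target = 120),
  camkii_blocked = list(kind = "disable_reactions", target = 51:55),
  pka_blocked = list(kind = "zero_species", target = "PKA"),
  pkc_blocked = list(kind = "zero_species", target = "PKC"),
  s845_deficient = list(kind = "disable_reactions", target = c(67, 68, 73)),
  s831_deficient = list(kind = "disable_reactions", target = 69:72),
  glur1_free = list(kind = "zero_species", target = c("GluR1", "GluR1_memb")),
  glur2_free = list(kind = "zero_species", target = c("GluR2", "GluR2_memb"))
)

#' Construct a network manipulation
#'
#' @param kind one of \code{"zero_species"} (initial concentration set to
#'   0), \code{"zero_flux_channel"} (an input channel is forced silent),
#'   \code{"disable_reactions"} (both rates of the named base reactions set
#'   to 0), \code{"scale_rate"} (forward and backward rates multiplied by
#'   \code{value}), or the name of a shipped preset (\code{"no_ca"},
#'   \code{"no_beta"}, \code{"no_ach"}, \code{"no_mglur"},
#'   \code{"camkii_blocked"}, \code{"pka_blocked"}, \code{"pkc_blocked"},
#'   \code{"s845_deficient"}, \code{"s831_deficient"}, \code{"glur1_free"},
#'   \code{"glur2_free"}).
#' @param target species name(s), channel name, or base reaction id(s).
#' @param value multiplier for \code{scale_rate}.
#' @return object of class \code{manipulation}.
#' @export
manipulation <- function(kind, target = NULL, value = NULL) {
  if (kind %in% names(MANIPULATION_PRESETS)) {
    m <- MANIPULATION_PRESETS[[kind]]
    m$preset <- kind
    return(structure(m, class = "manipulation"))
  }
  if (!kind %in% c("zero_species", "zero_flux_channel",
                   "disable_reactions", "scale_rate"))
    stop("unknown manipulation kind or preset: '", kind, "'")
  if (kind == "scale_rate" && (is.null(value) || any(value < 0)))
    stop("scale_rate requires a nonnegative value")
  structure(list(kind = kind, target = target, value = value),
            class = "manipulation")
}

#' Apply a manipulation to a network
#'
#' Manipulations compose: each call returns a new network, so presets can be
#' stacked (e.g. \code{s845_deficient} then \code{s831_deficient}).
#'
#' @param network a \code{reaction_network}.
#' @param m a \code{manipulation} or the name of a preset.
#' @return modified \code{reaction_network}.
#' @export
apply_manipulation <- function(network, m) {
  if (is.character(m)) m <- manipulation(m)
  stopifnot(inherits(m, "manipulation"))
  net <- network
  switch(m$kind,
    zero_species = {
      i <- species_index(net, m$target)
      net$species$init[i] <- 0
    },
    zero_flux_channel = {
      if (!m$target %in% names(net$channel_mask))
        stop("unknown input channel: ", m$target)
      net$channel_mask[m$target] <- 0
    },
    disable_reactions = {
      hit <- net$reactions$base_id %in% m$target
      if (!any(hit)) stop("no reactions with base id in {",
                          paste(m$target, collapse = ","), "}")
      net$reactions$kf[hit] <- 0
      net$reactions$kb[hit] <- 0
    },
    scale_rate = {
      hit <- net$reactions$base_id %in% m$target
      if (!any(hit)) stop("no reactions with base id in {",
                          paste(m$target, collapse = ","), "}")
      net$reactions$kf[hit] <- net$reactions$kf[hit] * m$value
      net$reactions$kb[hit] <- net$reactions$kb[hit] * m$value
    },
    stop("unknown manipulation kind: ", m$kind))
  net$metadata$manipulations <- c(net$metadata$manipulations,
                                  list(unclass(m)))
  net
}
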