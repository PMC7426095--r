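#' @keywords internal
"_PACKAGE"

# Canonical internal units: concentrations in nM, time in ms, volume in um^3.
AVOGADRO <- 6.02214076e23

#' Convert a particle flux to a concentration rate
#'
#' Inputs to the spine model are specified as particle fluxes
#' (particles/ms); the mass-action kinetics operate on concentrations (nM).
#' In a well-mixed compartment of volume \code{volume} um^3, one particle
#' corresponds to \code{1e24 / (N_A * volume)} nmol/L.
#'
#' @param amplitude particle flux, particles/ms (vectorised).
#' @param volume compartment volume in um^3.
#' @return concentration rate in nM/ms.
#' @examples
#' particles_to_concentration_rate(1, 0.5)   # ~3.32 nM/ms
#' @export
particles_to_concentration_rate <- function(amplitude, volume) {
  stopifnot(volume > 0)
  amplitude * 1e24 / (AVOGADRO * volume)
}

#' Convert a concentration to a subunit count
#'
#' Bridges species concentrations (nM) to the receptor-subunit counts used
#' by the tetramer statistics.
#'
#' @param concentration nM (vectorised).
#' @param volume compartment volume in um^3.
#' @return expected number of particles (real-valued).
#' @export
concentration_to_subunit_count <- function(concentration, volume) {
  stopifnot(volume > 0)
  concentration * AVOGADRO * volume * 1e-24
}

parse_side <- function(s) {
  s <- trimws(s)
  if (is.na(s) || s == "") return(integer(0))
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  out <- integer(0)
  for (tm in terms) {
    tm <- trimws(tm)
    if (tm == "") next
    if (grepl("*", tm, fixed = TRUE)) {
      bits <- strsplit(tm, "*", fixed = TRUE)[[1]]
      n <- suppressWarnings(as.integer(bits[1]))
      if (is.na(n) || n < 1) stop("bad stoichiometric prefix in term '", tm, "'")
      name <- trimws(bits[2])
    } else {
      n <- 1L
      name <- tm
    }
    out[name] <- (if (name %in% names(out)) out[[name]] else 0L) + n
  }
  out
}

subst_template <- function(template, X, Y, Z) {
  s <- gsub("@X", X, template, fixed = TRUE)
  s <- gsub("@Y", Y, s, fixed = TRUE)
  gsub("@Z", Z, s, fixed = TRUE)
}

#' Expand grouped reaction rows into elementary reactions
#'
#' The packaged reaction table keeps families of analogous reactions as
#' single rows with placeholders \code{@X}, \code{@Y}, \code{@Z}; the group
#' table lists, per row, the substitution tuple of every member. Expansion
#' yields one elementary mass-action reaction per member, all sharing the
#' row's forward/backward rates, and is idempotent (expanding an already
#' explicit table returns it unchanged).
#'
#' @param grouped data.frame with columns id, reactants, products, kf, kb,
#'   group, kb_law, note.
#' @param group_definitions data.frame with columns group, member, X, Y, Z.
#' @return data.frame of elementary reactions with columns id, base_id,
#'   member, reactants, products, kf, kb, kb_law, note.
#' @export
expand_reaction_groups <- function(grouped, group_definitions) {
  gd <- group_definitions
  for (col in c("X", "Y", "Z")) {
    if (!col %in% names(gd)) gd[[col]] <- ""
    gd[[col]][is.na(gd[[col]])] <- ""
  }
  rows <- vector("list", nrow(grouped))
  for (i in seq_len(nrow(grouped))) {
    r <- grouped[i, ]
    gid <- r$group
    if (is.na(gid) || gid == "") {
      base <- if ("base_id" %in% names(grouped)) r$base_id else
        suppressWarnings(as.integer(r$id))
      rows[[i]] <- data.frame(
        id = as.character(r$id), base_id = base, member = 1L,
        reactants = r$reactants, products = if (is.na(r$products)) "" else r$products,
        kf = r$kf, kb = r$kb, kb_law = r$kb_law, note = r$note,
        stringsAsFactors = FALSE)
    } else {
      mem <- gd[gd$group == gid, , drop = FALSE]
      if (nrow(mem) == 0L)
        stop("group '", gid, "' used by reaction ", r$id,
             " has no definition in the group table")
      mem <- mem[order(mem$member), , drop = FALSE]
      rows[[i]] <- do.call(rbind, lapply(seq_len(nrow(mem)), function(j) {
        m <- mem[j, ]
        data.frame(
          id = if (nrow(mem) > 1L) paste0(r$id, letters[m$member]) else as.character(r$id),
          base_id = as.integer(r$id), member = as.integer(m$member),
          reactants = subst_template(r$reactants, m$X, m$Y, m$Z),
          products = subst_template(if (is.na(r$products)) "" else r$products,
                                    m$X, m$Y, m$Z),
          kf = r$kf, kb = r$kb, kb_law = r$kb_law, note = r$note,
          stringsAsFactors = FALSE)
      }))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_network <- function(species, reactions) {
  if (anyDuplicated(species$name))
    stop("duplicate species name: ",
         species$name[duplicated(species$name)][1])
  if (any(species$init < 0))
    stop("negative initial concentration for species ",
         species$name[species$init < 0][1])
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    re <- parse_side(r$reactants)
    pr <- parse_side(r$products)
    unknown <- setdiff(c(names(re), names(pr)), species$name)
    if (length(unknown))
      stop("reaction ", r$id, " references unknown species '",
           unknown[1], "'")
    if (length(re) == 0L)
      stop("reaction ", r$id, " has no reactants")
    ord <- sum(re)
    if (ord < 1L || ord > 5L)
      stop("reaction ", r$id, " has reactant order ", ord,
           "; supported orders are 1-5")
    if (is.na(r$kf) || is.na(r$kb) || r$kf < 0 || r$kb < 0)
      stop("reaction ", r$id, " has a negative or missing rate")
  }
  invisible(TRUE)
}

#' Load the spine signalling network
#'
#' Reads the packaged model definition (species inventory with initial
#' concentrations, grouped reaction table, group memberships), expands the
#' grouped rows into elementary reactions, validates the result (no
#' dangling species, admissible reaction orders, nonnegative rates,
#' stoichiometric conservation of all closed molecular families) and checks
#' it against the frozen manifest.
#'
#' @param path \code{"builtin"} for the packaged model, or a directory
#'   containing \code{species.tsv}, \code{reactions.tsv} and
#'   \code{groups.tsv} in the same format.
#' @param volume compartment volume in um^3 (spine head, default 0.5).
#' @param check_manifest verify species/reaction counts against the packaged
#'   manifest (only for the builtin model).
#' @return an object of class \code{reaction_network}.
#' @examples
#' \donttest{
#' net <- load_model()
#' net
#' }
#' @export
load_model <- function(path = "builtin", volume = 0.5, check_manifest = TRUE) {
  builtin <- identical(path, "builtin")
  dir <- if (builtin) system.file("extdata", package = "spinedyn") else path
  read_tsv <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("model file not found: ", fp)
    utils::read.delim(fp, stringsAsFactors = FALSE, na.strings = NULL,
                      colClasses = "character")
  }
  species <- read_tsv("species.tsv")
  species$init <- as.numeric(species$init)
  grouped <- read_tsv("reactions.tsv")
  grouped$kf <- as.numeric(grouped$kf)
  grouped$kb <- as.numeric(grouped$kb)
  groups <- read_tsv("groups.tsv")
  groups$member <- as.integer(groups$member)

  reactions <- expand_reaction_groups(grouped, groups)
  validate_network(species, reactions)

  net <- structure(list(
    species = species,
    reactions = reactions,
    grouped = grouped,
    groups = groups,
    volume = volume,
    channel_mask = c(Ca = 1, L = 1, Glu = 1, ACh = 1),
    metadata = list(source = if (builtin) "builtin" else path)
  ), class = "reaction_network")

  fam <- conserved_families(net)
  check_conservation_symbolic(net, fam)

  if (builtin && check_manifest) {
    mf <- file.path(dir, "manifest.json")
    if (file.exists(mf)) {
      man <- jsonlite::read_json(mf)
      if (man$n_species != nrow(species) ||
          man$n_reactions != nrow(reactions))
        stop("builtin model does not match its manifest (",
             nrow(species), " species / ", nrow(reactions),
             " reactions; expected ", man$n_species, " / ",
             man$n_reactions, ")")
      fp <- network_fingerprint(net)
      if (!identical(man$fingerprint, fp))
        stop("builtin model fingerprint mismatch: ", fp)
    }
  }
  net
}

#' Deterministic fingerprint of an expanded network
#'
#' MD5 of the canonical serialisation of species initial concentrations and
#' the expanded reaction list; used in run manifests for provenance.
#' @param network a \code{reaction_network}.
#' @return character MD5 string.
#' @export
network_fingerprint <- function(network) {
  txt <- c(
    paste(network$species$name, format(network$species$init, digits = 15),
          sep = "="),
    paste(network$reactions$id, network$reactions$reactants,
          network$reactions$products,
          format(network$reactions$kf, digits = 15),
          format(network$reactions$kb, digits = 15), sep = "|"))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", nrow(x$species), "species,",
      nrow(x$reactions), "elementary reactions,",
      "volume", x$volume, "um^3\n")
  nz <- sum(x$species$init > 0)
  cat("  nonzero initial concentrations:", nz, "\n")
  if (any(x$channel_mask == 0))
    cat("  blocked input channels:",
        paste(names(x$channel_mask)[x$channel_mask == 0], collapse = ", "),
        "\n")
  invisible(x)
}

species_index <- function(network, names) {
  i <- match(names, network$species$name)
  if (anyNA(i)) stop("unknown species: ", names[is.na(i)][1])
  i
}

#' Initial state vector of a network
#' @param network a \code{reaction_network}.
#' @return named numeric vector of initial concentrations (nM).
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$init, network$species$name)
}
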