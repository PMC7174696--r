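# Metabolic reaction networks: construction, validation, I/O, stoichiometry.
#
# A network couples a metabolite table (id, name, role in {internal, external},
# compartment, carbon count) with a reaction table (id, reversible flag, and a
# sparse stoichiometry stored as a named numeric vector per reaction: negative
# coefficients are reactants, positive are products). External metabolites are
# exchange species: they are excluded from the steady-state balance, so an
# uptake reaction "GLCx -> GLC" leaves a free boundary at GLCx.

#' Construct a metabolic reaction network
#'
#' @param metabolites A data frame with columns `id`, `role`
#'   (`"internal"`/`"external"`) and optionally `name`, `compartment`,
#'   `carbon` (atoms of carbon, used by the carbon-return objective;
#'   unknown counts default to 0 with a warning).
#' @param reactions A data frame with columns `id`, `reversible` (logical) and
#'   `stoich`, a list-column of named numeric vectors (names are metabolite
#'   ids, negative = consumed, positive = produced).
#' @param biomass Id of the biomass reaction, or `NULL` if the network has
#'   none.
#' @return A validated object of class `rxn_network`.
#' @export
rxn_network <- function(metabolites, reactions, biomass = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "cytosol"
  if (!"carbon" %in% names(metabolites)) {
    warn("no `carbon` column in metabolite table; carbon counts default to 0")
    metabolites$carbon <- 0
  }
  metabolites$carbon[is.na(metabolites$carbon)] <- 0
  net <- structure(
    list(metabolites = metabolites, reactions = reactions, biomass = biomass),
    class = "rxn_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  mets <- net$metabolites
  rxns <- net$reactions
  if (anyDuplicated(mets$id)) {
    abort(paste0("duplicate metabolite id: ",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxns$id)) {
    abort(paste0("duplicate reaction id: ",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  }
  if (!all(mets$role %in% c("internal", "external"))) {
    abort("metabolite `role` must be \"internal\" or \"external\"")
  }
  if (any(mets$carbon < 0)) abort("carbon counts must be nonnegative")
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoich[[i]]
    if (length(st) == 0L) abort(paste0("reaction ", rxns$id[i], " has empty stoichiometry"))
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown) > 0L) {
      abort(paste0("reaction ", rxns$id[i], " references unknown metabolite ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(net$biomass) && !net$biomass %in% rxns$id) {
    abort(paste0("biomass reaction ", net$biomass, " not in network"))
  }
  invisible(net)
}

#' @export
print.rxn_network <- function(x, ...) {
  n_ext <- sum(x$metabolites$role == "external")
  cat("<rxn_network> ", nrow(x$reactions), " reactions (",
      sum(x$reactions$reversible), " reversible), ",
      nrow(x$metabolites) - n_ext, " internal + ", n_ext,
      " external metabolites\n", sep = "")
  if (!is.null(x$biomass)) cat("biomass reaction: ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' Tidy a reaction network into a long coefficient table
#'
#' @param x A `rxn_network`.
#' @param ... Unused.
#' @return A tibble with one row per (reaction, metabolite) coefficient.
#' @export
tidy.rxn_network <- function(x, ...) {
  purrr::map2_dfr(x$reactions$id, x$reactions$stoich, function(id, st) {
    tibble::tibble(reaction = id, metabolite = names(st), coefficient = unname(st))
  }) |>
    dplyr::left_join(
      dplyr::select(x$metabolites, metabolite = "id", "role", "carbon"),
      by = "metabolite"
    )
}

# ---- reaction equation strings -------------------------------------------

parse_equation <- function(eq, id = "?") {
  reversible <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    abort(paste0("reaction ", id, ": equation must contain one '->' or '<->': ", eq))
  }
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (tm in terms) {
      tm <- trimws(tm)
      if (tm == "") next
      m <- regmatches(tm, regexec("^([0-9.]+)\\s+(\\S+)$", tm))[[1]]
      coef <- if (length(m) == 3L) as.numeric(m[2]) else 1
      id <- if (length(m) == 3L) m[3] else tm
      prev <- if (id %in% names(out)) out[[id]] else 0
      out[id] <- sign * coef + prev
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  # merge duplicates across sides, drop exact cancellations
  st <- tapply(st, names(st), sum)
  st <- setNames(as.numeric(st), names(st))
  st <- st[st != 0]
  list(stoich = st, reversible = reversible)
}

format_equation <- function(st, reversible) {
  fmt <- function(v) {
    paste(purrr::map_chr(names(v), function(m) {
      cf <- abs(v[[m]])
      if (cf == 1) m else paste(format(cf), m)
    }), collapse = " + ")
  }
  lhs <- fmt(st[st < 0])
  rhs <- fmt(st[st > 0])
  paste(lhs, if (reversible) "<->" else "->", rhs)
}

# ---- I/O ------------------------------------------------------------------

#' Read a metabolic network from TSV or SBML
#'
#' The TSV dialect is a single tab-separated file with two sections headed by
#' `# metabolites` (columns `id`, `name`, `role`, `compartment`, `carbon`) and
#' `# reactions` (columns `id`, `equation`, `notes`), where equations are
#' written like `"2 A + B -> C"` with `"<->"` marking reversibility. SBML is
#' read from Level 3 core documents; species with `boundaryCondition="true"`
#' become external metabolites.
#'
#' @param path File path.
#' @param format `"tsv"` or `"sbml"`.
#' @param biomass Optional biomass reaction id to record on the network.
#' @return A validated `rxn_network`.
#' @export
read_network <- function(path, format = c("tsv", "sbml"), biomass = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("network file not found: ", path))
  if (format == "tsv") read_network_tsv(path, biomass) else read_network_sbml(path, biomass)
}

read_network_tsv <- function(path, biomass = NULL) {
  lines <- readLines(path)
  sec_met <- grep("^#\\s*metabolites", lines)
  sec_rxn <- grep("^#\\s*reactions", lines)
  if (length(sec_met) != 1L || length(sec_rxn) != 1L) {
    abort("TSV network needs one '# metabolites' and one '# reactions' section")
  }
  read_block <- function(from, to) {
    block <- lines[seq(from, to)]
    block <- block[nzchar(trimws(block)) & !grepl("^#", block)]
    utils::read.delim(text = paste(block, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (sec_met < sec_rxn) {
    mets <- read_block(sec_met + 1L, sec_rxn - 1L)
    rx <- read_block(sec_rxn + 1L, length(lines))
  } else {
    rx <- read_block(sec_rxn + 1L, sec_met - 1L)
    mets <- read_block(sec_met + 1L, length(lines))
  }
  parsed <- purrr::map2(rx$equation, rx$id, parse_equation)
  reactions <- tibble::tibble(
    id = rx$id,
    reversible = purrr::map_lgl(parsed, "reversible"),
    stoich = purrr::map(parsed, "stoich")
  )
  net <- rxn_network(mets, reactions, biomass = biomass)
  inform(paste0("read network: ", nrow(reactions), " reactions, ",
                sum(net$metabolites$role == "external"), " external + ",
                sum(net$metabolites$role == "internal"), " internal metabolites"))
  net
}

read_network_sbml <- function(path, biomass = NULL) {
  doc <- xml2::read_xml(path)
  ns_strip <- xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    role = ifelse(xml2::xml_attr(sp, "boundaryCondition") %in% "true",
                  "external", "internal"),
    compartment = dplyr::coalesce(xml2::xml_attr(sp, "compartment"), "cytosol"),
    carbon = 0
  )
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- purrr::map_dfr(rx, function(r) {
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(r, paste0("./", tag, "/speciesReference"))
      st <- sign * as.numeric(dplyr::coalesce(xml2::xml_attr(refs, "stoichiometry"), "1"))
      setNames(st, xml2::xml_attr(refs, "species"))
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    tibble::tibble(
      id = xml2::xml_attr(r, "id"),
      reversible = !(xml2::xml_attr(r, "reversible") %in% "false"),
      stoich = list(st)
    )
  })
  rxn_network(mets, reactions, biomass = biomass)
}

#' Write a network in the package's TSV dialect
#'
#' @param net A `rxn_network`.
#' @param path Output path.
#' @return `path`, invisibly. `read_network()` round-trips the file.
#' @export
write_network <- function(net, path) {
  mets <- net$metabolites[, c("id", "name", "role", "compartment", "carbon")]
  eqs <- purrr::map2_chr(net$reactions$stoich, net$reactions$reversible, format_equation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# metabolites", con)
  utils::write.table(mets, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# reactions", con)
  utils::write.table(
    data.frame(id = net$reactions$id, equation = eqs, notes = ""),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# ---- stoichiometry --------------------------------------------------------

#' Stoichiometric matrix of a network
#'
#' @param net A `rxn_network`.
#' @param rows `"internal"` (default; the steady-state balance rows),
#'   `"external"`, or `"all"`.
#' @return A dense matrix, metabolites in declaration order by row, reactions
#'   in declaration order by column.
#' @export
stoichiometric_matrix <- function(net, rows = c("internal", "external", "all")) {
  rows <- match.arg(rows)
  mets <- switch(rows,
    internal = net$metabolites$id[net$metabolites$role == "internal"],
    external = net$metabolites$id[net$metabolites$role == "external"],
    all = net$metabolites$id
  )
  S <- matrix(0, nrow = length(mets), ncol = nrow(net$reactions),
              dimnames = list(mets, net$reactions$id))
  for (j in seq_len(nrow(net$reactions))) {
    st <- net$reactions$stoich[[j]]
    keep <- names(st) %in% mets
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' Split reversible reactions into irreversible forward/reverse pairs
#'
#' Each reversible reaction `v` becomes `v` (forward) and `v_rev` (its
#' negation); the mapping back to signed fluxes on the original reactions is
#' kept in the `split_map` attribute (`split_id`, `orig_id`, `sign`).
#' Idempotent on fully irreversible networks.
#'
#' @param net A `rxn_network`.
#' @return A fully irreversible `rxn_network` with a `split_map` attribute.
#' @export
split_reversible <- function(net) {
  rxns <- net$reactions
  rows <- purrr::pmap_dfr(
    list(rxns$id, rxns$reversible, rxns$stoich),
    function(id, rev, st) {
      if (!rev) {
        tibble::tibble(id = id, reversible = FALSE, stoich = list(st),
                       orig = id, sign = 1)
      } else {
        orig_id <- id
        tibble::tibble(id = c(orig_id, paste0(orig_id, "_rev")),
                       reversible = FALSE, stoich = list(st, -st),
                       orig = orig_id, sign = c(1, -1))
      }
    }
  )
  out <- rxn_network(net$metabolites,
                     rows[, c("id", "reversible", "stoich")],
                     biomass = net$biomass)
  attr(out, "split_map") <- tibble::tibble(
    split_id = rows$id, orig_id = rows$orig, sign = rows$sign
  )
  out
}

# Recombine a nonnegative flux vector on the split network into a signed flux
# vector over the original reactions. Equal forward/reverse flux cancels.
recombine_flux <- function(v_split, split_map, orig_ids) {
  signed <- v_split * split_map$sign[match(names(v_split), split_map$split_id)]
  out <- tapply(signed, split_map$orig_id[match(names(v_split), split_map$split_id)], sum)
  res <- setNames(numeric(length(orig_ids)), orig_ids)
  res[names(out)] <- out
  res
}

#' Check elemental carbon balance of every reaction
#'
#' With fully specified carbon counts, internal conversions should conserve
#' carbon; boundary (exchange) and biomass reactions legitimately do not.
#' Violations are reported, not fatal, because carbon counts ship as a curated
#' side table rather than from formulas.
#'
#' @param net A `rxn_network`.
#' @return A tibble with per-reaction carbon imbalance and a `boundary` flag.
#' @export
carbon_balance <- function(net) {
  carbon <- setNames(net$metabolites$carbon, net$metabolites$id)
  role <- setNames(net$metabolites$role, net$metabolites$id)
  out <- purrr::map2_dfr(net$reactions$id, net$reactions$stoich, function(id, st) {
    tibble::tibble(
      reaction = id,
      imbalance = sum(st * carbon[names(st)]),
      boundary = any(role[names(st)] == "external") ||
        identical(id, net$biomass)
    )
  })
  bad <- dplyr::filter(out, !.data$boundary, abs(.data$imbalance) > 1e-9)
  if (nrow(bad) > 0L) {
    warn(paste0("carbon imbalance in non-boundary reactions: ",
                paste(bad$reaction, collapse = ", ")))
  }
  out
}
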