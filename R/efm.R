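# Elementary flux mode engine: enumeration (double description on the split
# network), import/export, directional-constraint filtering, and yields.
#
# Modes are stored signed over the ORIGINAL reactions (reverse sense =
# negative flux), one row per mode, each row scaled so its largest absolute
# entry is 1. Enumeration works on the irreversible split network with the
# classic Schuster/Hilgetag tableau: process one internal metabolite at a
# time, pairing positive against negative rows, and keep a combination only
# if no other row's zero set contains the pair's shared zero set.

new_em_set <- function(modes, net, provenance) {
  structure(list(modes = modes, network = net, provenance = provenance),
            class = "em_set")
}

#' @export
print.em_set <- function(x, ...) {
  cat("<em_set> ", nrow(x$modes), " elementary modes over ",
      ncol(x$modes), " reactions (", x$provenance[[1]], ")\n", sep = "")
  invisible(x)
}

#' Build an EM set from a flux matrix
#'
#' Validates each row against the steady-state balance and irreversibility
#' before wrapping; useful for hand-built fixtures and lumped-mode sets.
#'
#' @param modes Numeric matrix, one mode per row, columns named by reaction
#'   id (any order; reordered to the network's).
#' @param net The `rxn_network`.
#' @param tol Balance tolerance.
#' @return An `em_set` with provenance `"constructed"`.
#' @export
as_em_set <- function(modes, net, tol = 1e-6) {
  if (is.null(colnames(modes)) || !setequal(colnames(modes), net$reactions$id)) {
    abort("mode matrix columns must be the network's reaction ids")
  }
  modes <- modes[, net$reactions$id, drop = FALSE]
  S <- stoichiometric_matrix(net, rows = "internal")
  if (nrow(S) > 0L && nrow(modes) > 0L) {
    resid <- apply(abs(S %*% t(modes)), 2L, max)
    bad <- which(resid > tol * pmax(1, apply(abs(modes), 1L, max)))
    if (length(bad) > 0L) {
      abort(paste0("rows violate steady state: ", paste(bad, collapse = ", ")))
    }
  }
  irrev <- !net$reactions$reversible
  bad_dir <- which(apply(modes[, irrev, drop = FALSE], 1L, function(v) any(v < -tol)))
  if (length(bad_dir) > 0L) {
    abort(paste0("rows violate irreversibility: ", paste(bad_dir, collapse = ", ")))
  }
  new_em_set(modes, net, provenance = list("constructed"))
}

#' Number of modes in an EM set
#' @param ems An `em_set`.
#' @return Integer mode count.
#' @export
n_modes <- function(ems) nrow(ems$modes)

#' Tidy an EM set into a long flux table
#' @param x An `em_set`.
#' @param ... Unused.
#' @return A tibble with columns `mode`, `reaction`, `flux`.
#' @export
tidy.em_set <- function(x, ...) {
  m <- x$modes
  tibble::tibble(
    mode = rep(seq_len(nrow(m)), each = ncol(m)),
    reaction = rep(colnames(m), nrow(m)),
    flux = as.numeric(t(m))
  ) |> dplyr::filter(abs(.data$flux) > 0)
}

# canonicalize one signed mode: max-abs 1; if the mode's support is fully
# reversible (so its negation is also feasible) orient the first nonzero
# entry positive, making the +/- pair collapse to one representative.
canonical_mode <- function(v, reversible, tol = FLUX_TOL) {
  v[abs(v) <= tol] <- 0
  if (all(v == 0)) return(v)
  v <- normalize_mode(v)
  supp <- which(v != 0)
  if (all(reversible[supp]) && v[supp[1]] < 0) v <- -v
  v
}

dedup_modes <- function(M, tol = 1e-7) {
  if (nrow(M) <= 1L) return(M)
  keys <- apply(round(M, 7), 1L, paste, collapse = ",")
  M[!duplicated(keys), , drop = FALSE]
}

#' Enumerate elementary flux modes of a small network
#'
#' Runs a nullspace/tableau double-description enumeration on the split
#' (fully irreversible) network, removes the spurious forward/backward
#' two-cycles that splitting introduces, recombines to signed fluxes over the
#' original reactions, and canonicalizes each mode to max-abs-entry 1.
#'
#' @param net A `rxn_network`.
#' @param max_reactions Cap on the number of split-network columns the
#'   in-memory tableau will accept (default 32); larger sets should be
#'   computed externally and loaded with [import_efms()].
#' @return An `em_set`.
#' @export
enumerate_efms <- function(net, max_reactions = 32L) {
  sp <- split_reversible(net)
  smap <- attr(sp, "split_map")
  q <- nrow(sp$reactions)
  if (q > max_reactions) {
    abort(paste0("split network has ", q, " reactions (cap ", max_reactions,
                 "); enumerate externally and use import_efms()"))
  }
  S <- stoichiometric_matrix(sp, rows = "internal")
  # tableau: flux part (q cols) | balance part (rows of t(S))
  Tb <- cbind(diag(q), t(S))
  flux_cols <- seq_len(q)
  for (j in seq_len(nrow(S))) {
    col <- Tb[, q + j]
    zero <- abs(col) <= FLUX_TOL
    keep <- Tb[zero, , drop = FALSE]
    pos <- which(col > FLUX_TOL)
    neg <- which(col < -FLUX_TOL)
    new_rows <- list()
    if (length(pos) && length(neg)) {
      # zero-set masks over flux columns for the adjacency (minimality) test
      zmask <- abs(Tb[, flux_cols, drop = FALSE]) <= FLUX_TOL
      for (i in pos) {
        for (k in neg) {
          # adjacency: keep i+k only if no third row's zero set covers their
          # shared zero set (standard minimality test; an empty shared set is
          # covered by any third row, so such pairs are non-adjacent)
          shared <- zmask[i, ] & zmask[k, ]
          others <- setdiff(seq_len(nrow(Tb)), c(i, k))
          dominated <- length(others) > 0L &&
            any(rowSums(zmask[others, , drop = FALSE][, shared, drop = FALSE]) ==
                  sum(shared))
          if (!dominated) {
            r <- col[i] * Tb[k, ] - col[k] * Tb[i, ]
            new_rows[[length(new_rows) + 1L]] <- r / max(abs(r))
          }
        }
      }
    }
    Tb <- rbind(keep, do.call(rbind, new_rows))
    if (is.null(Tb) || nrow(Tb) == 0L) {
      Tb <- matrix(numeric(0), nrow = 0, ncol = q + nrow(S))
      break
    }
    Tb <- dedup_modes(Tb)
  }
  V <- Tb[, flux_cols, drop = FALSE]
  colnames(V) <- sp$reactions$id
  if (nrow(V) > 0L) {
    # drop split artifacts: modes supported on exactly a forward/reverse pair
    is_two_cycle <- apply(V, 1L, function(v) {
      supp <- colnames(V)[abs(v) > FLUX_TOL]
      origs <- smap$orig_id[match(supp, smap$split_id)]
      length(supp) == 2L && origs[1] == origs[2]
    })
    V <- V[!is_two_cycle, , drop = FALSE]
  }
  orig_ids <- net$reactions$id
  rev_flags <- net$reactions$reversible
  if (nrow(V) == 0L) {
    signed <- matrix(numeric(0), 0, length(orig_ids),
                     dimnames = list(NULL, orig_ids))
  } else {
    signed <- t(apply(V, 1L, function(v) {
      recombine_flux(setNames(v, colnames(V)), smap, orig_ids)
    }))
    signed <- t(apply(signed, 1L, canonical_mode, reversible = rev_flags))
    colnames(signed) <- orig_ids
    signed <- signed[rowSums(abs(signed)) > 0, , drop = FALSE]
    signed <- dedup_modes(signed)
  }
  new_em_set(signed, net, provenance = list("enumerated"))
}

# ---- import / export ------------------------------------------------------

#' Export an EM set as TSV (one mode per row, header = reaction ids)
#' @param ems An `em_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_efms <- function(ems, path) {
  utils::write.table(ems$modes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import an externally computed EM matrix
#'
#' Reads a TSV of flux vectors (header = reaction ids, one mode per row),
#' validates every row against the steady-state balance `S v = 0` and the
#' irreversibility constraints, and drops failing rows with their indices
#' reported. Reading is chunked so sets much larger than memory-resident
#' desk-scale problems stream through validation.
#'
#' @param path TSV path.
#' @param net The `rxn_network` the modes belong to.
#' @param tol Balance tolerance.
#' @param chunk_size Rows per validation chunk.
#' @param max_bad_frac Abort when more than this fraction of rows fail
#'   (defends against a wrong column order or dialect).
#' @return An `em_set`.
#' @export
import_efms <- function(path, net, tol = 1e-6, chunk_size = 50000L,
                        max_bad_frac = 0.01) {
  if (!file.exists(path)) abort(paste0("EM matrix not found: ", path))
  con <- file(path, "r")
  on.exit(close(con))
  header <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!setequal(header, net$reactions$id) || length(header) != nrow(net$reactions)) {
    abort(paste0("EM matrix columns do not match the network's ",
                 nrow(net$reactions), " reactions (dialect hint: header must ",
                 "be tab-separated reaction ids)"))
  }
  S <- stoichiometric_matrix(net, rows = "internal")
  S <- S[, header, drop = FALSE]
  irrev <- !net$reactions$reversible[match(header, net$reactions$id)]
  good <- list()
  bad_idx <- integer(0)
  row0 <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    M <- matrix(as.numeric(unlist(strsplit(lines, "\t", fixed = TRUE))),
                nrow = length(lines), byrow = TRUE)
    resid <- if (nrow(S) > 0) abs(S %*% t(M)) else
      matrix(0, 1, nrow(M))
    ok_bal <- apply(resid, 2L, max) <= tol * pmax(1, apply(abs(M), 1L, max))
    ok_dir <- apply(M[, irrev, drop = FALSE], 1L, function(v) all(v >= -tol))
    ok <- ok_bal & ok_dir
    bad_idx <- c(bad_idx, row0 + which(!ok))
    good[[length(good) + 1L]] <- M[ok, , drop = FALSE]
    row0 <- row0 + nrow(M)
  }
  if (length(bad_idx) > 0L) {
    if (length(bad_idx) > max_bad_frac * row0) {
      abort(paste0(length(bad_idx), "/", row0, " rows violate steady state or ",
                   "irreversibility; check the file dialect (columns must be ",
                   "the network's reaction ids, signed fluxes)"))
    }
    warn(paste0("dropped ", length(bad_idx), " invalid rows: ",
                paste(head(bad_idx, 10L), collapse = ", "),
                if (length(bad_idx) > 10L) ", ..."))
  }
  M <- do.call(rbind, good)
  colnames(M) <- header
  M <- M[, net$reactions$id, drop = FALSE]
  rev_flags <- net$reactions$reversible
  M <- t(apply(M, 1L, canonical_mode, reversible = rev_flags))
  if (length(M) && is.null(dim(M))) M <- matrix(M, nrow = 1)
  colnames(M) <- net$reactions$id
  new_em_set(dedup_modes(M), net, provenance = list("imported", path = path))
}

# ---- constraints ----------------------------------------------------------

#' Parse directional constraints written in the `v2r > 0` style
#'
#' A trailing `r` on an id that is not itself a reaction id means "the
#' reaction's reverse sense", i.e. net flux must be negative.
#'
#' @param x Character vector like `c("v87 > 0", "v2r > 0")`, or a data frame
#'   with columns `reaction`, `sense`.
#' @param net The network the constraints refer to.
#' @return A tibble with columns `reaction`, `sense` (`"positive"`/`"negative"`).
#' @export
parse_constraints <- function(x, net) {
  if (is.data.frame(x)) {
    out <- tibble::as_tibble(x)
  } else {
    ids <- trimws(sub(">.*$", "", x))
    sense <- rep("positive", length(ids))
    rev <- !(ids %in% net$reactions$id) & grepl("r$", ids) &
      sub("r$", "", ids) %in% net$reactions$id
    sense[rev] <- "negative"
    ids[rev] <- sub("r$", "", ids[rev])
    out <- tibble::tibble(reaction = ids, sense = sense)
  }
  unknown <- setdiff(out$reaction, net$reactions$id)
  if (length(unknown) > 0L) {
    abort(paste0("constraint references unknown reaction: ",
                 paste(unknown, collapse = ", ")))
  }
  out
}

#' Filter an EM set by directional constraints
#'
#' Retains exactly the modes whose net flux is strictly positive in the
#' stated sense (`> 1e-9` in magnitude) for every constraint.
#'
#' @param ems An `em_set`.
#' @param constraints Output of [parse_constraints()], a data frame with
#'   `reaction`/`sense` columns, or a character vector of `"v87 > 0"` forms.
#' @return A filtered `em_set`; provenance records the constraint list.
#' @export
filter_efms <- function(ems, constraints) {
  cons <- parse_constraints(constraints, ems$network)
  keep <- rep(TRUE, nrow(ems$modes))
  for (i in seq_len(nrow(cons))) {
    v <- ems$modes[, cons$reaction[i]]
    keep <- keep & if (cons$sense[i] == "positive") v > FLUX_TOL else v < -FLUX_TOL
  }
  new_em_set(ems$modes[keep, , drop = FALSE], ems$network,
             provenance = list("filtered", parent = ems$provenance[[1]],
                               constraints = cons))
}

# ---- yields ---------------------------------------------------------------

#' Per-mode yield vectors
#'
#' Yields are flux-magnitude ratios `|v_k| / |v_normalizer|` for an ordered
#' reaction subset; modes whose normalizer flux is (numerically) zero are not
#' in the yield space and get `in_yield_space = FALSE` with `NA` yields.
#'
#' @param ems An `em_set` (or a plain mode matrix with reaction columns).
#' @param reactions Ordered character vector of reaction ids to report.
#' @param normalizer Reaction whose flux magnitude divides all others;
#'   defaults to the network's biomass reaction.
#' @return A tibble: `mode`, `in_yield_space`, one column per yield.
#' @export
efm_yields <- function(ems, reactions, normalizer = NULL) {
  M <- if (inherits(ems, "em_set")) ems$modes else ems
  normalizer <- normalizer %||% ems$network$biomass
  if (is.null(normalizer)) abort("no normalizer reaction given and no biomass reaction set")
  miss <- setdiff(c(reactions, normalizer), colnames(M))
  if (length(miss)) abort(paste0("unknown reaction: ", paste(miss, collapse = ", ")))
  denom <- abs(M[, normalizer])
  ok <- denom > FLUX_TOL
  Y <- abs(M[, reactions, drop = FALSE]) / ifelse(ok, denom, NA_real_)
  out <- tibble::as_tibble(as.data.frame(Y))
  names(out) <- reactions
  dplyr::bind_cols(tibble::tibble(mode = seq_len(nrow(M)), in_yield_space = ok), out)
}

#' Test elementarity of a flux vector on a network
#'
#' A steady-state flux vector is elementary when the stoichiometric matrix
#' restricted to its support has a one-dimensional nullspace (rank test), so
#' no strictly smaller support carries a nonzero steady-state flux.
#'
#' @param net A `rxn_network`.
#' @param v Named (or network-ordered) signed flux vector.
#' @param tol Support tolerance.
#' @return Logical.
#' @export
is_elementary <- function(net, v, tol = FLUX_TOL) {
  S <- stoichiometric_matrix(net, rows = "internal")
  if (!is.null(names(v))) v <- v[colnames(S)]
  supp <- which(abs(v) > tol)
  if (length(supp) == 0L) return(FALSE)
  mat_rank(S[, supp, drop = FALSE]) == length(supp) - 1L
}
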