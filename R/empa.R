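# Elementary Mode Perturbation Analysis (EMPA): a minimal-adjustment walk
# through the polar EM cloud. Starting from a validated mode, repeatedly hop
# to the not-yet-visited mode that is closest in normalized polar coordinates
# (module scaled by the start mode's module, angles by 90 degrees) among
# those whose target-reaction yield moves strictly in the queried direction,
# until a stop rule fires. Mimics MOMA's minimal-metabolic-adjustment logic
# on the yield polytope.

#' A perturbation query
#'
#' @param target Reaction id whose yield is to be pushed.
#' @param direction `"increase"` or `"decrease"`.
#' @param stop_rule One of `"fold_change"` (stop when the target yield
#'   reaches `fold` times — or `1/fold` of — the start yield),
#'   `"angle_half"` (the target coordinate's polar angle reaches half its
#'   start value), `"knockout"` (target yield reaches 0).
#' @param fold Fold-change threshold (> 0), used by `"fold_change"`.
#' @return A list of class `perturbation_query`.
#' @export
perturbation_query <- function(target, direction = c("increase", "decrease"),
                               stop_rule = c("fold_change", "angle_half", "knockout"),
                               fold = 10) {
  direction <- match.arg(direction)
  stop_rule <- match.arg(stop_rule)
  if (fold <= 0) abort("fold must be > 0")
  structure(list(target = target, direction = direction,
                 stop_rule = stop_rule, fold = fold),
            class = "perturbation_query")
}

# angle of the target coordinate within a mode's polar description: the
# theta whose index is (position of target in ordering) - 1, i.e. the angle
# that introduces the target's yield into the prefix.
target_angle <- function(pol_row, ordering, target, ths) {
  j <- match(target, ordering) - 1L
  if (j < 1L) abort("target reaction must not be the first yield coordinate for angle-based stop rules")
  as.numeric(pol_row[[ths[j]]])
}

#' Walk a minimal-adjustment perturbation path
#'
#' @param ems An `em_set`.
#' @param start Mode index (row of the set) to start from — typically the
#'   PSYA-selected mode.
#' @param query A [perturbation_query()].
#' @param ordering Reaction ids spanning the yield space of the walk
#'   (defaults to every reaction except the normalizer); must contain the
#'   target.
#' @param normalizer Yield normalizer (default biomass).
#' @param step_cap Maximum number of steps (default 500).
#' @return A tibble of class `perturbation_path`: `step`, `mode`,
#'   `target_yield`, `fold_change`, `distance` (polar step distance), with
#'   attributes `reason` (termination) and `query`. The target yield is
#'   strictly monotone along the path; ties in distance break to the lowest
#'   mode index.
#' @export
perturbation_path <- function(ems, start, query, ordering = NULL,
                              normalizer = NULL, step_cap = 500L) {
  normalizer <- normalizer %||% ems$network$biomass
  ordering <- ordering %||% setdiff(colnames(ems$modes), normalizer)
  if (!query$target %in% ordering) {
    abort(paste0("target reaction ", query$target, " not in the yield ordering"))
  }
  pol <- polar_coords(ems, ordering, normalizer)
  ths <- grep("^theta", names(pol), value = TRUE)
  row0 <- which(pol$mode == start)
  if (length(row0) != 1L) abort("start mode is not in the yield space of the set")
  inc <- query$direction == "increase"
  y0 <- pol[[query$target]][row0]
  lam0 <- pol$lam[row0]
  if (!inc && y0 <= FLUX_TOL) {
    out <- tibble::tibble(step = integer(0), mode = integer(0),
                          target_yield = numeric(0), fold_change = numeric(0),
                          distance = numeric(0))
    attr(out, "reason") <- "already at knockout"
    attr(out, "query") <- query
    class(out) <- c("perturbation_path", class(out))
    return(out)
  }
  theta0 <- if (query$stop_rule == "angle_half") {
    target_angle(pol[row0, ], ordering, query$target, ths)
  } else NA_real_

  cur <- row0
  remaining <- setdiff(seq_len(nrow(pol)), row0)
  steps <- list(list(step = 0L, mode = pol$mode[row0], target_yield = y0,
                     fold_change = 1, distance = 0))
  reason <- "candidates exhausted"
  while (length(remaining) > 0L && length(steps) <= step_cap) {
    y_cur <- pol[[query$target]][cur]
    ok <- if (inc) pol[[query$target]][remaining] > y_cur + FLUX_TOL else
      pol[[query$target]][remaining] < y_cur - FLUX_TOL
    cand <- remaining[ok]
    if (length(cand) == 0L) {
      reason <- if (length(steps) == 1L) "no candidate in the queried direction"
      else "candidates exhausted"
      break
    }
    cur_pt <- list(lam = pol$lam[cur], theta = as.numeric(pol[cur, ths]))
    d <- vapply(cand, function(i) {
      polar_dist(list(lam = pol$lam[i], theta = as.numeric(pol[i, ths])),
                 cur_pt, lam0)
    }, numeric(1))
    nxt <- cand[which.min(d)] # ties: first = lowest mode index (pol is index-ordered)
    cur <- nxt
    remaining <- setdiff(remaining, nxt)
    y_new <- pol[[query$target]][cur]
    steps[[length(steps) + 1L]] <- list(
      step = length(steps), mode = pol$mode[cur], target_yield = y_new,
      fold_change = if (y0 > 0) y_new / y0 else Inf, distance = min(d)
    )
    hit <- switch(query$stop_rule,
      fold_change = if (inc) y_new >= query$fold * y0 else y_new <= y0 / query$fold,
      knockout = y_new <= FLUX_TOL,
      angle_half = {
        th <- target_angle(pol[cur, ], ordering, query$target, ths)
        if (inc) th >= 90 - (90 - theta0) / 2 else th <= theta0 / 2
      }
    )
    if (isTRUE(hit)) { reason <- "stop rule reached"; break }
    if (length(steps) > step_cap) { reason <- "step cap reached"; break }
  }
  out <- dplyr::bind_rows(purrr::map(steps, tibble::as_tibble))
  attr(out, "reason") <- reason
  attr(out, "query") <- query
  attr(out, "ordering") <- ordering
  attr(out, "normalizer") <- normalizer
  class(out) <- c("perturbation_path", class(out))
  out
}

#' Tabulate tracked-reaction yields along a perturbation path
#'
#' Reports, per step, the yields of a set of tracked reactions against the
#' target's fold change, plus the least-squares slope of each tracked yield
#' with respect to the target yield (the "apparent linear relationship"
#' summary). Slopes are `NA` with a note for single-step paths.
#'
#' @param path A `perturbation_path`.
#' @param ems The `em_set` the path walks through.
#' @param tracked Reaction ids to report.
#' @return A tibble `step`, `mode`, `fold_change`, `target_yield`, one
#'   column per tracked reaction; the `slopes` attribute holds a tibble
#'   `reaction`, `slope`.
#' @export
path_report <- function(path, ems, tracked) {
  if (nrow(path) == 0L) abort("empty path")
  missing_r <- setdiff(tracked, colnames(ems$modes))
  if (length(missing_r) > 0L) {
    abort(paste0("tracked reaction not in network: ",
                 paste(missing_r, collapse = ", ")))
  }
  normalizer <- attr(path, "normalizer")
  yl <- efm_yields(ems, tracked, normalizer)
  rows <- yl[match(path$mode, yl$mode), tracked, drop = FALSE]
  out <- dplyr::bind_cols(
    path[, c("step", "mode", "fold_change", "target_yield")], rows
  )
  slopes <- purrr::map_dfr(tracked, function(r) {
    sl <- if (nrow(out) < 2L) NA_real_ else
      unname(coef(lm(out[[r]] ~ out$target_yield))[2])
    tibble::tibble(reaction = r, slope = sl)
  })
  if (nrow(out) < 2L) {
    inform("single-step path: slopes undefined, reported as NA")
  }
  attr(out, "slopes") <- slopes
  out
}
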