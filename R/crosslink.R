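#' Maximal bridging span of a bis-MTS cross-linker
#'
#' Bifunctional methanethiosulfonate (MTS) reagents MnM carry an n-methylene
#' spacer between two thiol-reactive heads. Their maximal C-beta--C-beta
#' bridging span grows linearly with spacer length:
#' `span_max = 2.6 + 1.3 * n` Angstrom, the unique line through the published
#' M3M (6.5 A) and M8M (13 A) anchors, which also reproduces the M17M anchor
#' (24.7 A). The minimal comfortable span defaults to `span_max / 2`: the
#' flexible chain can fold back to bridge closer pairs, at reduced
#' efficiency.
#'
#' @param n_methylene Integer spacer length(s), >= 1.
#' @param span_min_fraction Fraction of `span_max` taken as `span_min`.
#' @return Tibble with columns `n_methylene`, `span_min`, `span_max` (A).
#' @examples
#' reagent_span(c(3, 8, 17))
#' @export
reagent_span <- function(n_methylene, span_min_fraction = 0.5) {
  n <- as.integer(n_methylene)
  if (any(n < 1)) abort("n_methylene must be >= 1")
  span_max <- (26 + 13 * n) / 10    # exact at the printed precision
  tibble(n_methylene = n, span_min = span_min_fraction * span_max,
         span_max = span_max)
}

#' Default cross-linker reagent panel
#'
#' The bifunctional MnM series used for pairwise cysteine cross-linking, with
#' spans from [reagent_span()]. Monofunctional reagents (e.g. MTSBn) may be
#' present in observation tables but are excluded from distance-based
#' prediction, since their effect (pore blockage) is not a distance
#' phenomenon.
#'
#' @param n_methylene Spacer lengths to include.
#' @return Tibble with columns `reagent`, `n_methylene`, `span_min`,
#'   `span_max`, `monofunctional`.
#' @export
reagent_panel <- function(n_methylene = c(1, 2, 3, 5, 8, 17)) {
  sp <- reagent_span(n_methylene)
  tibble(reagent = paste0("M", sp$n_methylene, "M"),
         n_methylene = sp$n_methylene,
         span_min = sp$span_min,
         span_max = sp$span_max,
         monofunctional = FALSE)
}

#' Classify residue-pair / reagent compatibility
#'
#' Converts distance statistics into per-reagent bridging calls:
#' \describe{
#'   \item{spontaneous_disulfide}{`d <= d_ss` (default 2.1 A): the cysteines
#'     can form a direct S-S bond without reagent.}
#'   \item{bridgeable_full}{`span_min <= d <= span_max + tol_full`.}
#'   \item{bridgeable_partial}{`d < span_min` (chain fold-back) or
#'     `d <= span_max + tol_partial`.}
#'   \item{not_bridgeable}{beyond every window: a fully extended linker
#'     cannot reach.}
#' }
#' The default upper tolerances are small (0.2 A, printed-value rounding): a
#' reagent cannot span farther than its extended length. Pairs whose mean
#' separation exceeds a span but that approach transiently can be assessed
#' with `use = "min"`.
#'
#' @param distances Distance summary from [pair_distances()] (columns `id`,
#'   `state`, `mean`, `min`), or any tibble with those columns.
#' @param panel Reagent panel from [reagent_panel()].
#' @param d_ss Spontaneous-disulfide threshold (A).
#' @param tol_full Upper tolerance on the full-efficiency window (A).
#' @param tol_partial Upper tolerance on the partial window (A).
#' @param use Drive classification by the ensemble `"mean"` distance
#'   (default) or the per-frame `"min"`.
#' @return Tibble of class `plx_calls`: `id`, `state`, `reagent`, `d`,
#'   `span_min`, `span_max`, `call`.
#' @export
classify_crosslink <- function(distances, panel = reagent_panel(),
                               d_ss = 2.1, tol_full = 0.2, tol_partial = 0.2,
                               use = c("mean", "min")) {
  use <- match.arg(use)
  stopifnot(d_ss > 0)
  panel <- filter(as_tibble(panel), !.data$monofunctional)
  dist_tab <- as_tibble(distances)
  if (!"state" %in% names(dist_tab)) dist_tab$state <- "other"
  dist_tab$d_used <- if (use == "min") dist_tab$min else dist_tab$mean

  out <- tidyr::crossing(select(dist_tab, "id", "state", d = "d_used"),
                         select(panel, "reagent", "span_min", "span_max")) %>%
    mutate(call = crosslink_call(.data$d, .data$span_min, .data$span_max,
                                 d_ss, tol_full, tol_partial)) %>%
    arrange(.data$id, .data$state, .data$reagent)
  class(out) <- c("plx_calls", class(out))
  out
}

crosslink_call <- function(d, span_min, span_max, d_ss, tol_full, tol_partial) {
  dplyr::case_when(
    d <= d_ss ~ "spontaneous_disulfide",
    d >= span_min & d <= span_max + tol_full ~ "bridgeable_full",
    d < span_min ~ "bridgeable_partial",
    d <= span_max + tol_partial ~ "bridgeable_partial",
    TRUE ~ "not_bridgeable"
  )
}

call_rank <- function(call) {
  match(call, c("not_bridgeable", "bridgeable_partial", "bridgeable_full",
                "spontaneous_disulfide"))
}

#' Conformer-resolved bridging prediction
#'
#' Classifies every (pair, reagent) combination in each conformational state
#' and aggregates across states: the aggregate call per reagent is the best
#' call over states (spontaneous/full > partial > none), annotated with the
#' state(s) that support it. A reagent may thus bridge only the closed
#' conformer of a pair that is too far apart in the open one.
#'
#' @param distances_by_state Distance summary containing multiple `state`
#'   labels (e.g. the row-bound OWF and IWF series), or a named list of
#'   per-state summaries.
#' @param panel Reagent panel.
#' @param ... Passed to [classify_crosslink()].
#' @return A list of class `plx_prediction` with `per_state` calls and
#'   `aggregate` (tibble: `id`, `reagent`, `call`, `via_states`).
#' @export
predict_bridging <- function(distances_by_state, panel = reagent_panel(), ...) {
  if (is.list(distances_by_state) && !is.data.frame(distances_by_state)) {
    distances_by_state <- imap(distances_by_state,
                               ~ mutate(as_tibble(.x), state = .y)) %>% list_rbind()
  }
  per_state <- classify_crosslink(distances_by_state, panel, ...)
  aggregate <- per_state %>%
    group_by(.data$id, .data$reagent) %>%
    summarise(
      via_states = paste(sort(unique(
        .data$state[call_rank(.data$call) == max(call_rank(.data$call))])),
        collapse = ","),
      call = .data$call[which.max(call_rank(.data$call))],
      .groups = "drop") %>%
    select("id", "reagent", "call", "via_states")
  structure(list(per_state = per_state, aggregate = aggregate),
            class = "plx_prediction")
}

#' @export
print.plx_prediction <- function(x, ...) {
  cat("<cross-link bridging prediction>",
      length(unique(x$aggregate$id)), "pairs x",
      length(unique(x$aggregate$reagent)), "reagents\n")
  n_bridge <- x$aggregate %>% group_by(.data$id) %>%
    summarise(b = any(.data$call != "not_bridgeable")) %>% pull("b") %>% sum()
  cat("  pairs predicted bridgeable by at least one reagent:", n_bridge, "\n")
  invisible(x)
}

#' Read a cross-linking observation table from TSV
#'
#' Columns: `id`, `reagent`, `observed` with outcomes from
#' `{none, partial, full}`.
#' @param path TSV path.
#' @return Observation tibble.
#' @export
read_observation_table <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE)
  check_observations(obs)
  obs
}

check_observations <- function(obs) {
  stopifnot(all(c("id", "reagent", "observed") %in% names(obs)))
  bad <- setdiff(unique(obs$observed), c("none", "partial", "full"))
  if (length(bad) > 0) {
    abort(paste0("observation outcomes must be none/partial/full; found: ",
                 paste(bad, collapse = ", ")))
  }
  dup <- obs %>% dplyr::count(.data$id, .data$reagent) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate observation rows for pair ", dup$id[1],
                 " with reagent ", dup$reagent[1]))
  }
  invisible(obs)
}

#' Concordance between predicted and observed cross-linking
#'
#' Compares predictions and observations at the pair level: a pair is
#' concordant when "any reagent predicted bridgeable" matches "any reagent
#' observed to cross-link". Also returns a per-reagent confusion table at the
#' none-vs-any level. Observation rows with no matching prediction are
#' reported, never silently dropped.
#'
#' @param predictions A `plx_prediction` (or its aggregate tibble).
#' @param observations Observation tibble (`id`, `reagent`, `observed`).
#' @return A list of class `plx_concordance`: `per_pair`, `n_concordant`,
#'   `n_tested`, `concordance` (fraction), `per_reagent` confusion tibble,
#'   `unmatched` observation rows.
#' @export
crosslink_concordance <- function(predictions, observations) {
  agg <- if (inherits(predictions, "plx_prediction")) predictions$aggregate
         else as_tibble(predictions)
  obs <- check_observations(as_tibble(observations))

  unmatched <- anti_join(obs, agg, by = "id")
  matched <- semi_join(obs, agg, by = "id")

  pred_pair <- agg %>% group_by(.data$id) %>%
    summarise(predicted_bridgeable = any(.data$call != "not_bridgeable"),
              .groups = "drop")
  obs_pair <- matched %>% group_by(.data$id) %>%
    summarise(observed_crosslink = any(.data$observed != "none"),
              .groups = "drop")
  per_pair <- inner_join(pred_pair, obs_pair, by = "id") %>%
    mutate(concordant = .data$predicted_bridgeable == .data$observed_crosslink)

  per_reagent <- inner_join(
    matched,
    select(agg, "id", "reagent", "call"),
    by = c("id", "reagent")) %>%
    mutate(pred_any = .data$call != "not_bridgeable",
           obs_any = .data$observed != "none") %>%
    group_by(.data$reagent) %>%
    summarise(tp = sum(.data$pred_any & .data$obs_any),
              fp = sum(.data$pred_any & !.data$obs_any),
              fn = sum(!.data$pred_any & .data$obs_any),
              tn = sum(!.data$pred_any & !.data$obs_any),
              .groups = "drop")

  structure(list(per_pair = per_pair,
                 n_concordant = sum(per_pair$concordant),
                 n_tested = nrow(per_pair),
                 concordance = mean(per_pair$concordant),
                 per_reagent = per_reagent,
                 unmatched = unmatched),
            class = "plx_concordance")
}

#' @export
print.plx_concordance <- function(x, ...) {
  cat(sprintf("<cross-link concordance> %d/%d pairs concordant (%.1f%%)\n",
              x$n_concordant, x$n_tested, 100 * x$concordance))
  if (nrow(x$unmatched) > 0) {
    cat("  ", nrow(x$unmatched), "observation rows had no prediction\n")
  }
  invisible(x)
}

#' @method glance plx_concordance
#' @export
glance.plx_concordance <- function(x, ...) {
  tibble(n_tested = x$n_tested, n_concordant = x$n_concordant,
         concordance = x$concordance, n_unmatched = nrow(x$unmatched))
}
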