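#' Build a residue-pair table
#'
#' @param id Pair identifiers (e.g. `"S341-T1134"`).
#' @param chain_a,resno_a,chain_b,resno_b Chain and author residue number of
#'   each partner.
#' @param helix_a,helix_b Optional helix labels (e.g. `"TMH6"`, `"TMH12"`).
#' @return A tibble usable by [pair_distances()].
#' @export
residue_pairs <- function(id, chain_a, resno_a, chain_b, resno_b,
                          helix_a = NA_character_, helix_b = NA_character_) {
  out <- tibble(id = id, chain_a = chain_a, resno_a = as.integer(resno_a),
                chain_b = chain_b, resno_b = as.integer(resno_b),
                helix_a = helix_a, helix_b = helix_b)
  same <- out$chain_a == out$chain_b & out$resno_a == out$resno_b
  if (any(same)) abort(paste0("pair ", out$id[which(same)[1]],
                              " pairs a residue with itself"))
  out
}

#' Read a residue-pair list from TSV
#'
#' Columns: `id`, `chain_a`, `resno_a`, `chain_b`, `resno_b` and optionally
#' `helix_a`, `helix_b`.
#' @param path TSV file path.
#' @return A residue-pair tibble.
#' @export
read_pair_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          chain_a = readr::col_character(),
                          chain_b = readr::col_character(),
                          .default = readr::col_guess()))
  col_or_na <- function(nm) if (nm %in% names(df)) df[[nm]] else NA_character_
  residue_pairs(df$id, df$chain_a, df$resno_a, df$chain_b, df$resno_b,
                col_or_na("helix_a"), col_or_na("helix_b"))
}

#' Per-frame C-beta distances for residue pairs
#'
#' Computes the C-beta--C-beta distance (virtual C-beta for glycine) for each
#' pair in every frame and summarises per pair: mean, population standard
#' deviation, minimum and maximum. State labels (e.g. OWF/IWF) are metadata
#' supplied by the caller, not inferred from the coordinates.
#'
#' @param ensemble Atom tibble (see [read_pdb()]).
#' @param pairs Residue-pair tibble from [residue_pairs()].
#' @param state State label attached to every row (default `"other"`).
#' @param atom Reference point: `"CB"` (default) or `"CA"`.
#' @return A tibble of class `plx_distance_series` with one row per pair:
#'   `id`, `state`, `mean`, `sd`, `min`, `max`, `n_frames`, and a list-column
#'   `d` holding the per-frame distances in frame order.
#' @export
pair_distances <- function(ensemble, pairs, state = "other",
                           atom = c("CB", "CA")) {
  atom <- match.arg(atom)
  present <- distinct(as_tibble(ensemble)[, c("chain", "resno")])
  pkey <- paste(present$chain, present$resno)
  for (i in seq_len(nrow(pairs))) {
    for (side in c("a", "b")) {
      k <- paste(pairs[[paste0("chain_", side)]][i],
                 pairs[[paste0("resno_", side)]][i])
      if (!k %in% pkey) {
        abort(paste0("pair ", pairs$id[i], ": residue ", k,
                     " is not resolvable in the ensemble"))
      }
    }
  }
  res <- dplyr::bind_rows(
    tibble(chain = pairs$chain_a, resno = pairs$resno_a),
    tibble(chain = pairs$chain_b, resno = pairs$resno_b)
  ) %>% distinct()
  pts <- if (atom == "CB") {
    cbeta_points(ensemble, residues = res)
  } else {
    ca <- semi_join(filter(ensemble, .data$atom == "CA"), res,
                    by = c("chain", "resno"))
    transmute(ca, frame = .data$frame, chain = .data$chain,
              resno = .data$resno, x = .data$x, y = .data$y, z = .data$z)
  }
  frames <- sort(unique(ensemble$frame))
  key <- function(chain, resno, frame) paste(chain, resno, frame)
  lookup <- setNames(seq_len(nrow(pts)), key(pts$chain, pts$resno, pts$frame))

  out <- pmap(pairs, function(id, chain_a, resno_a, chain_b, resno_b, ...) {
    ia <- lookup[key(chain_a, resno_a, frames)]
    ib <- lookup[key(chain_b, resno_b, frames)]
    if (any(is.na(ia)) || any(is.na(ib))) {
      f <- frames[which(is.na(ia) | is.na(ib))[1]]
      abort(paste0("pair ", id, ": residue not resolvable in frame ", f))
    }
    d <- sqrt((pts$x[ia] - pts$x[ib])^2 + (pts$y[ia] - pts$y[ib])^2 +
              (pts$z[ia] - pts$z[ib])^2)
    tibble(id = id, state = state, mean = mean(d), sd = pop_sd(d),
           min = min(d), max = max(d), n_frames = length(d), d = list(d))
  }) %>% list_rbind()
  class(out) <- c("plx_distance_series", class(out))
  out
}

#' Interface stability assessment
#'
#' A residue-pair distance series is flagged stable when its standard
#' deviation over the ensemble stays at or below a threshold; a small SD for
#' all pairs across an interface indicates the interface holds together over
#' the trajectory.
#'
#' @param series Distance summary from [pair_distances()].
#' @param sd_threshold Stability threshold in Angstrom.
#' @return A list with `pairs` (tibble adding a `stable` flag) and
#'   `fraction_stable`.
#' @export
interface_stability <- function(series, sd_threshold = 1.5) {
  if (nrow(series) == 0) abort("empty distance series")
  tab <- mutate(as_tibble(series), stable = .data$sd <= sd_threshold)
  list(pairs = select(tab, -dplyr::any_of("d")),
       fraction_stable = mean(tab$stable),
       sd_threshold = sd_threshold)
}

#' Write a distance summary to TSV
#' @param series Output of [pair_distances()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(series, path) {
  readr::write_tsv(select(as_tibble(series), -dplyr::any_of("d")), path)
  invisible(path)
}

#' @method autoplot plx_distance_series
#' @export
autoplot.plx_distance_series <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$id, y = .data$mean,
                                    colour = .data$state)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "Cβ–Cβ distance (Å)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
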