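# Integration-event calling: junction inference, orientation-aware target
# assignment, and deduplication by (target, distance, truncation, extras).
#
# The integration distance is the number of bases strictly between the
# element's 5'-terminal nucleotide and the target's +1; non-templated extra
# nucleotides are element-side and excluded from the distance. Target-site
# duplication bases count as genomic.

#' Calling parameters
#'
#' @param max_assign_distance Junctions farther than this from the nearest
#'   facing target are left unassigned (default 250 bp, comfortably above
#'   the observed 23-181 bp integration window).
#' @param require_orientation Enforce orientation-specific integration (the
#'   element 5' end must face the target's 5' end; default `TRUE`).
#' @return A list of class `call_params`.
#' @export
call_params <- function(max_assign_distance = 250L, require_orientation = TRUE) {
  stopifnot(max_assign_distance >= 1)
  structure(list(max_assign_distance = as.integer(max_assign_distance),
                 require_orientation = isTRUE(require_orientation)),
            class = "call_params")
}

#' Infer the junction from an accepted placement
#'
#' The fragment is stored junction-first (gene sense), so its first aligned
#' base is the genomic base adjacent to the element 5' terminus: plus-strand
#' placements put the junction at the alignment start, minus-strand
#' placements at the alignment end. Fragment bases before the alignment
#' start are the resolved non-templated extras.
#'
#' @param placements Placement tibble (accepted, `category ==
#'   "target_genome"`) from [map_fragments()].
#' @param frags Fragment tibble (supplies `genomic_part`, `truncation`).
#' @return Tibble `read_id`, `ref_id`, `junction` (plus-strand coordinate of
#'   the first aligned genomic base), `facing` (strand the element faces
#'   along), `extras`, `truncation`, `group_placement`, `duplicate_group`.
#' @export
infer_junction <- function(placements, frags) {
  pl <- placements[placements$accepted & placements$category == "target_genome", , drop = FALSE]
  fr <- frags[match(pl$read_id, frags$read_id), , drop = FALSE]
  tibble::tibble(
    read_id = pl$read_id,
    ref_id = pl$ref_id,
    junction = ifelse(pl$strand == "+", pl$start, pl$end),
    facing = pl$strand,
    extras = substr(fr$genomic_part, 1L, pl$q_start - 1L),
    truncation = fr$truncation,
    group_placement = pl$group_placement,
    duplicate_group = pl$duplicate_group
  )
}

#' Assign junctions to catalog targets
#'
#' Selects the nearest catalog target downstream of the junction on the
#' junction's facing strand; the distance is the count of bases strictly
#' between the element 5' terminus (excluding extras) and the target's +1.
#' Junctions farther than `max_assign_distance`, or facing away from every
#' nearby target when `require_orientation` is set, stay unassigned.
#'
#' @param junctions Tibble from [infer_junction()].
#' @param catalog Target catalog tibble.
#' @param params A [call_params()] object.
#' @return The junction tibble with `target_id`, `target_group`, `distance`
#'   and `assign_status` (`assigned`, `wrong_orientation`, `too_far`,
#'   `no_target`) columns.
#' @export
assign_target <- function(junctions, catalog, params = call_params()) {
  n <- nrow(junctions)
  target_id <- rep(NA_character_, n); target_group <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n); status <- rep("no_target", n)
  for (i in seq_len(n)) {
    j <- junctions$junction[i]; ref <- junctions$ref_id[i]; facing <- junctions$facing[i]
    cand <- catalog[catalog$ref_id == ref, , drop = FALSE]
    if (!nrow(cand)) next
    d <- ifelse(cand$strand == "+", cand$plus_one - j, j - cand$plus_one)
    ok <- d >= 1L
    facing_ok <- cand$strand == facing
    sel <- ok & (!params$require_orientation | facing_ok)
    if (!any(sel)) {
      # a target within reach but facing the wrong way is informative
      near_wrong <- ok & !facing_ok & d <= params$max_assign_distance
      status[i] <- if (any(near_wrong)) "wrong_orientation" else "no_target"
      next
    }
    best <- which(sel)[which.min(d[sel])]
    if (d[best] > params$max_assign_distance) {
      status[i] <- "too_far"
      next
    }
    target_id[i] <- cand$target_id[best]
    target_group[i] <- if (junctions$group_placement[i] && !is.na(junctions$duplicate_group[i])) {
      junctions$duplicate_group[i]
    } else cand$duplicate_group[best]
    distance[i] <- as.integer(d[best])
    status[i] <- "assigned"
  }
  dplyr::bind_cols(junctions,
                   tibble::tibble(target_id = target_id, target_group = target_group,
                                  distance = distance, assign_status = status))
}

#' Deduplicate assigned junctions into integration events
#'
#' Reads collapse into one event when they agree on (target or duplicate
#' group, distance, 5' truncation, extras): insertions at exactly the same
#' position are distinguishable only by their truncation and/or
#' non-templated extra nucleotides. Single-read events are retained but
#' flagged.
#'
#' @param assigned Tibble from [assign_target()] (rows with
#'   `assign_status == "assigned"` are used).
#' @param library_type Library label carried into the events.
#' @return Events tibble: `target_group`, `target_id` (representative),
#'   `distance`, `truncation`, `extras`, `read_support`, `library_type`,
#'   `single_read`.
#' @export
deduplicate_events <- function(assigned, library_type = "tdna") {
  ok <- assigned[assigned$assign_status == "assigned", , drop = FALSE]
  if (!nrow(ok)) {
    return(tibble::tibble(target_group = character(0), target_id = character(0),
                          distance = integer(0), truncation = integer(0),
                          extras = character(0), read_support = integer(0),
                          library_type = character(0), single_read = logical(0)))
  }
  ok |>
    dplyr::group_by(.data$target_group, .data$distance, .data$truncation, .data$extras) |>
    dplyr::summarise(target_id = dplyr::first(.data$target_id),
                     read_support = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(library_type = library_type, single_read = .data$read_support == 1L) |>
    dplyr::relocate("target_group", "target_id", "distance", "truncation",
                    "extras", "read_support", "library_type", "single_read") |>
    dplyr::arrange(.data$target_group, .data$distance, .data$truncation, .data$extras)
}

#' Call integration events from placements
#'
#' Wrapper: [infer_junction()], [assign_target()], [deduplicate_events()].
#'
#' @param map_result A `tre_map` from [map_fragments()].
#' @param frags Fragment tibble.
#' @param catalog Target catalog.
#' @param params A [call_params()] object.
#' @param library_type Library label.
#' @return A list of class `tre_calls`: `events`, `assigned` (per-read
#'   assignments), `counts` (per-reason tallies).
#' @export
call_integrations <- function(map_result, frags, catalog, params = call_params(),
                              library_type = "tdna") {
  junctions <- infer_junction(map_result$placements, frags)
  assigned <- assign_target(junctions, catalog, params)
  events <- deduplicate_events(assigned, library_type)
  counts <- assigned |> dplyr::count(.data$assign_status, name = "count")
  structure(list(events = events, assigned = assigned, counts = counts),
            class = "tre_calls")
}

#' Write events as BED6+ TSV
#'
#' @param events Events tibble; positions are not carried (events are keyed
#'   by target), so the BED interval anchors at the target's +1.
#' @param catalog Catalog (for coordinates).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, catalog, path) {
  idx <- match(events$target_id, catalog$target_id)
  bed <- tibble::tibble(
    chrom = catalog$ref_id[idx],
    chromStart = catalog$plus_one[idx] - 1L,
    chromEnd = catalog$plus_one[idx],
    name = paste0(events$target_group, ":", events$distance, ":",
                  events$truncation, ":", ifelse(nzchar(events$extras), events$extras, "-")),
    score = events$read_support,
    strand = catalog$strand[idx],
    distance = events$distance,
    truncation = events$truncation,
    extras = ifelse(nzchar(events$extras), events$extras, "."),
    support = events$read_support,
    library = events$library_type
  )
  readr::write_lines("# treprofiler integration events (BED6+); +1-anchored", path)
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Compare called events against a planted truth table
#'
#' Truth records are aggregated by the same key as called events (duplicate
#' group, distance, truncation, extras); recall is the fraction of truth
#' keys recovered, precision the fraction of called events that are planted.
#'
#' @param events Events tibble from [deduplicate_events()].
#' @param truth Truth tibble from [plant_integrations()].
#' @return A one-row tibble: `n_truth`, `n_called`, `n_matched`, `recall`,
#'   `precision`, `exact_multiset` (called keys identical to truth keys).
#' @export
evaluate_against_truth <- function(events, truth) {
  key <- function(g, d, t, x) paste(g, d, t, ifelse(is.na(x) | x == "", ".", x), sep = "|")
  tkeys <- unique(key(truth$duplicate_group, truth$distance, truth$truncation, truth$extras))
  ckeys <- unique(key(events$target_group, events$distance, events$truncation, events$extras))
  n_matched <- length(intersect(tkeys, ckeys))
  tibble::tibble(
    n_truth = length(tkeys), n_called = length(ckeys), n_matched = n_matched,
    recall = if (length(tkeys)) n_matched / length(tkeys) else NA_real_,
    precision = if (length(ckeys)) n_matched / length(ckeys) else NA_real_,
    exact_multiset = setequal(tkeys, ckeys)
  )
}
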