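# Profiling summaries: integration-distance distribution and window
# fraction, target occupancy and overlap with a prior element population,
# hot-spot (read-count bias) summary, and per-stage read accounting.

#' Distance window specification
#'
#' @param center Window centre in bp (default 47, the modal integration
#'   distance upstream of tRNA genes).
#' @param halfwidth Half-width in bp (default 3).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(center = 47L, halfwidth = 3L) {
  stopifnot(center >= 1, halfwidth >= 0)
  structure(list(center = as.integer(center), halfwidth = as.integer(halfwidth)),
            class = "window_spec")
}

#' Integration-distance distribution
#'
#' Per-distance event and read counts.
#'
#' @param events Events tibble (see [deduplicate_events()]).
#' @return Tibble `distance`, `n_events`, `n_reads`, sorted by distance.
#' @export
distance_distribution <- function(events) {
  if (!nrow(events)) {
    return(tibble::tibble(distance = integer(0), n_events = integer(0), n_reads = integer(0)))
  }
  events |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(n_events = dplyr::n(), n_reads = sum(.data$read_support),
                     .groups = "drop") |>
    dplyr::arrange(.data$distance)
}

#' Fraction of events inside a distance window
#'
#' @param events Events tibble.
#' @param window A [window_spec()] (default 47 +/- 3 bp).
#' @return Fraction of events with `|distance - center| <= halfwidth`;
#'   `NA` (with a message) when there are no events.
#' @export
fraction_in_window <- function(events, window = window_spec()) {
  if (!nrow(events)) {
    message("no events: window fraction not available")
    return(NA_real_)
  }
  mean(abs(events$distance - window$center) <= window$halfwidth)
}

#' Per-target occupancy and overlap with a prior population
#'
#' Marks each catalog target as untargeted, targeted, or targeted-and-prior;
#' with several runs (a named list of event tibbles) a per-run logical
#' column is added and `targeted` means targeted in the union.
#'
#' @param catalog Target catalog tibble.
#' @param events Events tibble or named list of event tibbles.
#' @param prior_targets Optional character vector of target ids occupied by
#'   the pre-existing element population.
#' @return Tibble `target_id`, one logical column per run, `targeted`,
#'   `status`; summary counts in the `"summary"` attribute (`n_targeted`,
#'   `n_prior`, `n_overlap_prior`, `n_union`).
#' @export
occupancy_matrix <- function(catalog, events, prior_targets = NULL) {
  runs <- if (is.data.frame(events)) list(run1 = events) else events
  stopifnot(length(runs) >= 1)
  out <- tibble::tibble(target_id = catalog$target_id)
  hit_any <- rep(FALSE, nrow(out))
  for (nm in names(runs)) {
    ids <- unique(stats::na.omit(runs[[nm]]$target_id))
    # a duplicate-group call occupies every member of the group
    grp <- unique(stats::na.omit(runs[[nm]]$target_group))
    hit <- out$target_id %in% ids | catalog$duplicate_group %in% grp
    out[[nm]] <- hit
    hit_any <- hit_any | hit
  }
  prior <- out$target_id %in% (prior_targets %||% character(0))
  out$targeted <- hit_any
  out$status <- dplyr::case_when(
    hit_any & prior ~ "targeted_and_prior",
    hit_any ~ "targeted",
    TRUE ~ "untargeted"
  )
  attr(out, "summary") <- tibble::tibble(
    n_targeted = sum(hit_any),
    n_prior = sum(prior),
    n_overlap_prior = sum(hit_any & prior),
    n_union = sum(hit_any)
  )
  out
}

#' Hot-spot (read-count bias) summary
#'
#' Compares per-locus read counts with the expected average under a uniform
#' distribution over the catalog: loci strictly above the average are
#' counted, and their share of all reads reported.
#'
#' @param locus_counts Numeric vector of mapped read counts per targeted
#'   locus, or a tibble with a `read_count` (or `n_reads`) column.
#' @param n_catalog_targets Number of potential targets the reads could have
#'   distributed over (denominator of the expected average).
#' @return One-row tibble: `total_reads`, `expected_average` (exact),
#'   `expected_average_display` (rounded to integer), `n_above_average`,
#'   `read_share_of_above` (percent).
#' @export
hotspot_summary <- function(locus_counts, n_catalog_targets) {
  if (is.data.frame(locus_counts)) {
    col <- intersect(c("read_count", "n_reads"), names(locus_counts))[1]
    stopifnot(!is.na(col))
    locus_counts <- locus_counts[[col]]
  }
  stopifnot(n_catalog_targets >= 1)
  total <- sum(locus_counts)
  avg <- total / n_catalog_targets
  above <- locus_counts > avg    # strictly above the expected average
  share <- if (total > 0) 100 * sum(locus_counts[above]) / total else 0
  tibble::tibble(
    total_reads = total,
    expected_average = avg,
    expected_average_display = as.integer(round(avg)),
    n_above_average = sum(above),
    read_share_of_above = share
  )
}

#' Per-stage read accounting
#'
#' Rebuilds the library-summary table (read pairs, assembled pseudoreads,
#' element-mapped, primer/adapter-retained, length-filtered, genome-mapped,
#' target-assigned, plasmid/promoter, palindrome, remaining) and a terminal
#' partition in which every assembled pseudoread falls in exactly one
#' category, so counts are conserved.
#'
#' @param prep A `tre_prep` from [prep_reads()].
#' @param map_result A `tre_map` from [map_fragments()].
#' @param calls A `tre_calls` from [call_integrations()].
#' @param refs Reference tibble (to split palindrome from chromosomes).
#' @param catalog Target catalog.
#' @return A list with `table` (stage counts in pipeline order) and
#'   `terminal` (category, count; sums to assembled pseudoreads).
#' @export
stage_accounting <- function(prep, map_result, calls, refs, catalog) {
  all <- prep$all
  assembled <- all$status %in% setdiff(unique(all$status), c("no_overlap", "short_pseudoread"))
  terminal <- rep(NA_character_, nrow(all))
  terminal[all$status == "no_primer"] <- "no_primer"
  terminal[all$status == "no_element"] <- "no_element"
  terminal[all$status == "ambiguous_junction"] <- "ambiguous_junction"
  terminal[all$status == "short_fragment"] <- "short_fragment"
  live <- which(all$status == "merged")
  pl <- map_result$placements
  asg <- calls$assigned
  pal_refs <- refs$ref_id[refs$kind == "palindrome_arm"]
  for (i in live) {
    id <- all$read_id[i]
    p <- pl[pl$read_id == id, , drop = FALSE]
    if (!nrow(p) || !p$accepted[1]) { terminal[i] <- "unplaced"; next }
    if (p$category[1] == "plasmid_actin6") { terminal[i] <- "plasmid_actin6"; next }
    a <- asg[asg$read_id == id, , drop = FALSE]
    if (nrow(a) && a$assign_status[1] == "assigned") {
      terminal[i] <- if (p$ref_id[1] %in% pal_refs) "palindrome_assigned" else "target_assigned"
    } else {
      terminal[i] <- "mapped_unassigned"
    }
  }
  term <- tibble::tibble(category = terminal[assembled]) |>
    dplyr::count(.data$category, name = "count")

  n_pairs <- prep$counts$count[prep$counts$stage == "read_pairs"]
  n_assembled <- sum(assembled)
  n_element <- sum(assembled & !all$status %in% c("no_primer", "no_element"))
  n_trimmed <- sum(assembled & all$status %in% c("merged", "short_fragment") & all$primer_found)
  n_ge40 <- sum(all$status == "merged")
  n_mapped <- sum(pl$accepted)
  n_assigned <- sum(terminal == "target_assigned", na.rm = TRUE)
  n_plasmid <- sum(terminal == "plasmid_actin6", na.rm = TRUE)
  n_pal <- sum(terminal == "palindrome_assigned", na.rm = TRUE)
  n_remaining <- n_assembled - n_assigned - n_plasmid - n_pal -
    sum(terminal %in% c("no_primer", "no_element", "ambiguous_junction", "short_fragment"), na.rm = TRUE)
  tab <- tibble::tibble(
    stage = c("read_pairs", "assembled_pseudoreads", "element_mapped",
              "primer_adapter_trimmed", "fragments_ge_min_len",
              "mapped_to_reference", "assigned_to_targets",
              "plasmid_promoter", "palindrome_assigned", "remaining"),
    count = c(n_pairs, n_assembled, n_element, n_trimmed, n_ge40,
              n_mapped, n_assigned, n_plasmid, n_pal, n_remaining)
  )
  list(table = tab, terminal = term)
}
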