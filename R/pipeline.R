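# Pipeline orchestration: a flat run configuration, file-based subcommands
# (simulate / catalog / prep / map / call / report / all) and an in-memory
# wrapper returning a `tre_profile` result object with broom-style methods.

#' Run configuration
#'
#' A flat configuration bundling every stage's parameters plus the seed and
#' output directory. Every default matches the stated pipeline value where
#' one exists (minimum pseudoread length 100 nt, minimum fragment 40 nt,
#' second-best ratio 0.75, query coverage 0.95, A/B spacing 30-60 bp, +1
#' offset 7 bp, distance window 47 +/- 3 bp).
#'
#' @param seed Integer seed for all stochastic stages.
#' @param library_type `"tdna"` or `"adapter"`.
#' @param outdir Output directory for file-based subcommands.
#' @param sim A [sim_params()] object.
#' @param prep A [prep_params()] object.
#' @param map A [map_params()] object.
#' @param call A [call_params()] object.
#' @param catalog A [catalog_params()] object.
#' @param window A [window_spec()].
#' @param element An [element_model()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, library_type = c("tdna", "adapter"),
                       outdir = tempfile("treprofiler_run_"),
                       sim = NULL, prep = prep_params(), map = map_params(),
                       call = call_params(), catalog = catalog_params(),
                       window = window_spec(), element = element_model()) {
  library_type <- match.arg(library_type)
  if (is.null(sim)) sim <- sim_params(library_type = library_type, seed = seed)
  sim$library_type <- library_type
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), library_type = library_type,
                 outdir = outdir, sim = sim, prep = prep, map = map,
                 call = call, catalog = catalog, window = window,
                 element = element),
            class = "run_config")
}

#' Write / read a flat key-value configuration file
#'
#' Only scalar simulation and filter keys are serialised (`key = value`, one
#' per line, `#` comments); unknown keys are rejected by the reader.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return The path (writer); a [run_config()] (reader).
#' @export
write_config <- function(config, path) {
  s <- config$sim
  kv <- c(
    seed = config$seed, library_type = config$library_type,
    genome_len = s$genome_len, gc_content = s$gc_content,
    n_trna_genes = s$n_trna_genes, n_events = s$n_events,
    error_rate = s$error_rate, read_len = s$read_len,
    background_fraction = s$background_fraction,
    p_truncation = s$p_truncation, p_extra_nt = s$p_extra_nt,
    min_pseudoread_len = config$prep$min_pseudoread_len,
    min_trimmed_len = config$prep$min_trimmed_len,
    second_best_ratio = config$map$second_best_ratio,
    min_query_coverage = config$map$min_query_coverage,
    max_assign_distance = config$call$max_assign_distance,
    spacing_min = config$catalog$spacing_min,
    spacing_max = config$catalog$spacing_max
  )
  readr::write_lines(c("# treprofiler run configuration",
                       paste(names(kv), "=", kv)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\\s*=\\s*", 2)
  kv <- stats::setNames(parts[, 2], trimws(parts[, 1]))
  known <- c("seed", "library_type", "genome_len", "gc_content", "n_trna_genes",
             "n_events", "error_rate", "read_len", "background_fraction",
             "p_truncation", "p_extra_nt", "min_pseudoread_len", "min_trimmed_len",
             "second_best_ratio", "min_query_coverage", "max_assign_distance",
             "spacing_min", "spacing_max")
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  num <- function(k, d) if (k %in% names(kv)) as.numeric(kv[[k]]) else d
  seed <- as.integer(num("seed", 1))
  lib <- if ("library_type" %in% names(kv)) kv[["library_type"]] else "tdna"
  sim <- sim_params(
    genome_len = num("genome_len", 100000), gc_content = num("gc_content", 0.25),
    n_trna_genes = num("n_trna_genes", 40), n_events = num("n_events", 250),
    error_rate = num("error_rate", 0.001), read_len = num("read_len", 300),
    background_fraction = num("background_fraction", 0.1),
    p_truncation = num("p_truncation", 0.25), p_extra_nt = num("p_extra_nt", 0.5),
    library_type = lib, seed = seed
  )
  run_config(
    seed = seed, library_type = lib, sim = sim,
    prep = prep_params(min_pseudoread_len = num("min_pseudoread_len", 100),
                       min_trimmed_len = num("min_trimmed_len", 40)),
    map = map_params(second_best_ratio = num("second_best_ratio", 0.75),
                     min_query_coverage = num("min_query_coverage", 0.95)),
    call = call_params(max_assign_distance = num("max_assign_distance", 250)),
    catalog = catalog_params(spacing_min = num("spacing_min", 30),
                             spacing_max = num("spacing_max", 60))
  )
}

#' Run the whole pipeline in memory
#'
#' Simulates (or accepts) data, prepares reads, maps junction fragments,
#' calls integration events and computes the profiling summaries.
#'
#' @param config A [run_config()].
#' @param reads Optional `tre_reads` (or pairs tibble) to profile instead of
#'   simulating; requires `genome`.
#' @param genome Optional `tre_genome` (references, catalog, primers).
#' @return A `tre_profile` object: `events`, `assigned`, `placements`,
#'   `stage` accounting, `distance_hist`, `window_fraction`, `hotspot`,
#'   `occupancy`, `truth` and `truth_eval` (when simulated), `config`.
#' @export
run_pipeline <- function(config = run_config(), reads = NULL, genome = NULL) {
  if (is.null(genome)) {
    genome <- make_genome(config$sim, element = config$element, seed = config$seed,
                          catalog_parameters = config$catalog)
  }
  truth <- NULL
  if (is.null(reads)) {
    sim <- plant_integrations(genome, seed = config$seed)
    reads <- simulate_amplicons(sim, seed = config$seed)
    truth <- reads$truth
  }
  prep <- prep_reads(reads, genome$element, config$library_type,
                     primers = genome$primers, params = config$prep)
  index <- index_references(genome$refs, config$map)
  mapres <- map_fragments(prep$fragments, index, genome$catalog, config$map,
                          max_assign_distance = config$call$max_assign_distance)
  calls <- call_integrations(mapres, prep$fragments, genome$catalog,
                             config$call, config$library_type)
  acc <- stage_accounting(prep, mapres, calls, genome$refs, genome$catalog)
  events <- calls$events
  locus_reads <- events |>
    dplyr::group_by(.data$target_group) |>
    dplyr::summarise(read_count = sum(.data$read_support), .groups = "drop")
  res <- list(
    events = events,
    assigned = calls$assigned,
    placements = mapres$placements,
    stage = acc$table,
    terminal = acc$terminal,
    distance_hist = distance_distribution(events),
    window_fraction = fraction_in_window(events, config$window),
    hotspot = hotspot_summary(locus_reads, nrow(genome$catalog)),
    occupancy = occupancy_matrix(genome$catalog, events),
    catalog = genome$catalog,
    truth = truth,
    truth_eval = if (!is.null(truth)) evaluate_against_truth(events, truth) else NULL,
    config = config
  )
  structure(res, class = "tre_profile")
}

#' @export
print.tre_profile <- function(x, ...) {
  g <- glance(x)
  cat("<tre_profile>\n")
  cat(sprintf("  %d read pairs -> %d pseudoreads -> %d events at %d targets\n",
              g$n_read_pairs, g$n_pseudoreads, g$n_events, g$n_targets_hit))
  cat(sprintf("  fraction in %d+/-%d bp window: %.3f\n",
              x$config$window$center, x$config$window$halfwidth, g$window_fraction))
  if (!is.null(x$truth_eval)) {
    cat(sprintf("  vs truth: recall %.3f, precision %.3f\n",
                x$truth_eval$recall, x$truth_eval$precision))
  }
  invisible(x)
}

#' Tidy an integration profile
#'
#' @param x A `tre_profile`.
#' @param ... Unused.
#' @return The events tibble (one row per deduplicated integration event).
#' @export
tidy.tre_profile <- function(x, ...) x$events

#' One-row summary of an integration profile
#'
#' @param x A `tre_profile`.
#' @param ... Unused.
#' @return A one-row tibble with read, event, occupancy, window and (when
#'   simulated) truth-recovery summaries.
#' @export
glance.tre_profile <- function(x, ...) {
  st <- stats::setNames(x$stage$count, x$stage$stage)
  out <- tibble::tibble(
    n_read_pairs = unname(st["read_pairs"]),
    n_pseudoreads = unname(st["assembled_pseudoreads"]),
    n_fragments = sum(x$placements$accepted | !x$placements$accepted),
    n_mapped = unname(st["mapped_to_reference"]),
    n_events = nrow(x$events),
    n_targets_hit = dplyr::n_distinct(x$events$target_group),
    window_fraction = x$window_fraction,
    hotspot_read_share = x$hotspot$read_share_of_above
  )
  if (!is.null(x$truth_eval)) {
    out$recall <- x$truth_eval$recall
    out$precision <- x$truth_eval$precision
  }
  out
}

#' Plot the integration-distance histogram
#'
#' @param object A `tre_profile`.
#' @param ... Unused.
#' @return A ggplot: event counts per distance with the acceptance window
#'   shaded.
#' @export
autoplot.tre_profile <- function(object, ...) {
  w <- object$config$window
  ggplot2::ggplot(object$distance_hist,
                  ggplot2::aes(x = .data$distance, y = .data$n_events)) +
    ggplot2::annotate("rect", xmin = w$center - w$halfwidth - 0.5,
                      xmax = w$center + w$halfwidth + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "distance to target +1 (bp)", y = "integration events",
                  title = "Integration distances",
                  subtitle = sprintf("window %d±%d bp", w$center, w$halfwidth)) +
    ggplot2::theme_minimal()
}

#' Plot target occupancy
#'
#' @param profile A `tre_profile`.
#' @return A ggplot tile map of per-target occupancy status.
#' @export
plot_occupancy <- function(profile) {
  occ <- profile$occupancy |>
    dplyr::mutate(idx = dplyr::row_number(),
                  col = (.data$idx - 1L) %% 20L,
                  row = (.data$idx - 1L) %/% 20L)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(untargeted = "grey85",
                                          targeted = "firebrick",
                                          targeted_and_prior = "darkorange")) +
    ggplot2::labs(title = "Target occupancy", x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

# ---- file-based subcommands ---------------------------------------------------

#' Run a pipeline subcommand against files
#'
#' `simulate` writes references, catalog, truth and FASTQ; `catalog` builds
#' an A/B-box catalog from a reference FASTA; `prep`, `map` and `call` chain
#' through TSV/FASTA intermediates; `report` writes the summary tables;
#' `all` runs everything in memory and writes all artifacts. Logs record the
#' package version, seed and key parameters.
#'
#' @param name One of `simulate`, `catalog`, `prep`, `map`, `call`,
#'   `report`, `all`.
#' @param config A [run_config()].
#' @return Invisibly, the output directory.
#' @export
run_subcommand <- function(name = c("all", "simulate", "catalog", "prep", "map",
                                    "call", "report"),
                           config = run_config()) {
  name <- match.arg(name)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  log_line <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ..., "\n"),
                                file = logf, append = TRUE)
  log_line("treprofiler ", as.character(utils::packageVersion("treprofiler")),
           " subcommand=", name, " seed=", config$seed,
           " library=", config$library_type)

  p <- function(f) file.path(out, f)
  if (name %in% c("simulate", "all")) {
    genome <- make_genome(config$sim, element = config$element, seed = config$seed,
                          catalog_parameters = config$catalog)
    sim <- plant_integrations(genome, seed = config$seed)
    reads <- simulate_amplicons(sim, seed = config$seed)
    write_refs_fasta(genome$refs, p("refs.fasta"))
    write_target_catalog(genome$catalog, p("catalog.bed"))
    readr::write_tsv(genome$primers, p("primers.tsv"))
    write_truth(reads$truth, p("truth.tsv"), seed = config$seed)
    write_fastq_pairs(reads, p("reads_R1.fastq"), p("reads_R2.fastq"))
    write_config(config, p("config.txt"))
    log_line("simulated ", nrow(reads$truth), " events, ", nrow(reads$pairs), " read pairs")
    if (name == "simulate") return(invisible(out))
  }
  if (name == "catalog") {
    refs <- read_refs_fasta(p("refs.fasta"))
    ab <- build_ab_box_catalog(refs, config$catalog)
    ab <- group_duplicate_loci(ab, refs, config$catalog)
    write_target_catalog(ab, p("ab_catalog.bed"))
    write_solo_b_report(ab, p("solo_b_boxes.txt"))
    log_line("ab-box catalog: ", nrow(ab), " targets")
    return(invisible(out))
  }
  if (name == "all") {
    profile <- run_pipeline(config, reads = reads, genome = genome)
    profile$truth <- reads$truth
    profile$truth_eval <- evaluate_against_truth(profile$events, reads$truth)
    write_events(profile$events, genome$catalog, p("events.bed"))
    readr::write_tsv(profile$assigned, p("assigned.tsv"))
    readr::write_tsv(profile$placements, p("placements.tsv"))
    readr::write_tsv(profile$stage, p("stage_counts.tsv"))
    readr::write_tsv(profile$distance_hist, p("distance_hist.tsv"))
    readr::write_tsv(profile$occupancy, p("occupancy.tsv"))
    write_run_summary(profile, p("summary.tsv"))
    log_line("called ", nrow(profile$events), " events")
    return(invisible(out))
  }
  # prep / map / call / report chain through files written by earlier stages
  genome <- list(
    refs = read_refs_fasta(p("refs.fasta")),
    catalog = read_target_catalog(p("catalog.bed")),
    primers = readr::read_tsv(p("primers.tsv"), show_col_types = FALSE),
    element = config$element, params = config$sim
  )
  class(genome) <- "tre_genome"
  if (name == "prep") {
    pairs <- read_fastq_pairs(p("reads_R1.fastq"), p("reads_R2.fastq"))
    prep <- prep_reads(pairs, genome$element, config$library_type,
                       primers = genome$primers, params = config$prep)
    write_fragments(prep, p("fragments.fasta"))
    readr::write_tsv(prep$counts, p("prep_counts.tsv"))
    log_line("prep: ", nrow(prep$fragments), " fragments retained")
    return(invisible(out))
  }
  prep <- read_fragments(p("fragments.fasta"))
  index <- index_references(genome$refs, config$map)
  mapres <- map_fragments(prep$fragments, index, genome$catalog, config$map,
                          max_assign_distance = config$call$max_assign_distance)
  if (name == "map") {
    readr::write_tsv(mapres$placements, p("placements.tsv"))
    log_line("map: ", sum(mapres$placements$accepted), " fragments placed")
    return(invisible(out))
  }
  calls <- call_integrations(mapres, prep$fragments, genome$catalog,
                             config$call, config$library_type)
  if (name == "call") {
    write_events(calls$events, genome$catalog, p("events.bed"))
    readr::write_tsv(calls$assigned, p("assigned.tsv"))
    log_line("call: ", nrow(calls$events), " events")
    return(invisible(out))
  }
  # report
  acc <- stage_accounting(prep, mapres, calls, genome$refs, genome$catalog)
  readr::write_tsv(acc$table, p("stage_counts.tsv"))
  readr::write_tsv(distance_distribution(calls$events), p("distance_hist.tsv"))
  frac <- fraction_in_window(calls$events, config$window)
  readr::write_lines(c("# treprofiler run summary",
                       paste0("window_fraction = ", frac)), p("summary.tsv"))
  invisible(out)
}

# Fragments as FASTA with structured headers (read id, truncation, extras
# candidate deferred, trimmed primer) so prep output round-trips.
write_fragments <- function(prep, path) {
  fr <- prep$fragments
  x <- Biostrings::DNAStringSet(fr$genomic_part)
  names(x) <- sprintf("%s trunc=%d elem=%d primer=%s lib=%s",
                      fr$read_id, fr$truncation, fr$element_len,
                      ifelse(is.na(fr$trimmed_primer), ".", fr$trimmed_primer),
                      prep$library_type)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_fragments <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  fld <- function(key) {
    v <- stringr::str_match(nm, paste0(key, "=(\\S+)"))[, 2]
    v
  }
  fr <- tibble::tibble(
    read_id = sub("\\s.*", "", nm),
    genomic_part = as.character(x),
    truncation = as.integer(fld("trunc")),
    element_len = as.integer(fld("elem")),
    trimmed_primer = dplyr::na_if(fld("primer"), "."),
    status = "merged"
  )
  lib <- unique(fld("lib")); lib <- lib[!is.na(lib)]
  counts <- tibble::tibble(stage = c("read_pairs", "fragments_out"),
                           count = c(NA_integer_, nrow(fr)))
  structure(list(fragments = fr, all = dplyr::mutate(fr, primer_found = !is.na(fr$trimmed_primer)),
                 counts = counts,
                 library_type = if (length(lib)) lib[1] else "tdna"),
            class = "tre_prep")
}

#' Write the machine-readable run summary
#'
#' Key-value TSV used for downstream checks: stage counts, event counts,
#' window fraction, hot-spot share, and truth recovery when available.
#'
#' @param profile A `tre_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_summary <- function(profile, path) {
  g <- glance(profile)
  kv <- c(
    as.list(stats::setNames(profile$stage$count, profile$stage$stage)),
    n_events = nrow(profile$events),
    n_targets_hit = g$n_targets_hit,
    window_fraction = profile$window_fraction,
    hotspot_read_share = profile$hotspot$read_share_of_above,
    seed = profile$config$seed
  )
  if (!is.null(profile$truth_eval)) {
    kv$recall <- profile$truth_eval$recall
    kv$precision <- profile$truth_eval$precision
  }
  readr::write_lines(c("# treprofiler run summary",
                       paste0(names(kv), "\t", unlist(kv))), path)
  invisible(path)
}
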