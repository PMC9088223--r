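# End-to-end design pipeline: surface selection, seed generation, overlap
# graph, path sampling, fusion, scoring, filtering and per-cluster selection.

#' Design run configuration
#'
#' Collects every stage's parameters with the pipeline defaults. Unknown
#' names are rejected.
#'
#' @param ... name = value overrides of the defaults.
#' @return a `design_config`.
#' @export
design_config <- function(...) {
  cfg <- list(
    n_min_matches = 10,         # fragment growth / match budget
    rmsd_cutoff = 1.0,          # fragment match cutoff, Angstrom
    multi_segment = FALSE,
    flank = 2,                  # seed flank, residues
    surface_cutoff = 0.05,      # relative SASA above which a residue is surface
    window_len = 4,             # overlap window, residues
    max_ca_dist = 0.75,         # overlap CA bound, Angstrom
    max_frame_angle = 30,       # overlap orientation bound, degrees
    clash_scale = 0.7,
    n_paths = 50,               # accepted paths to sample
    min_length = 15,            # minimum path length, residues
    contacts_cutoff = 2.5,      # contacts-per-residue filter
    score_cutoff = 0.2,         # TERM interface score filter
    cluster_threshold = 5.0,    # selection cluster RMSD, Angstrom
    cluster_threshold_coarse = 20.0,
    per_cluster = 3,
    score_ref_size = 500,
    rng_seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "design_config")
}

#' Run the full peptide-backbone design pipeline
#'
#' Generates seeds around the binding site (or the whole protein surface),
#' builds the overlap graph, samples paths, fuses them into candidate
#' backbones, scores each by potential contacts per residue and the TERM
#' interface score, clusters, filters and selects up to `per_cluster` designs
#' per cluster. Fully reproducible from the config's `rng_seed`.
#'
#' @param target list of `backbone_chain` (the target protein).
#' @param db a `structure_db`.
#' @param site binding-site residue set (2-column matrix into `target`), or
#'   NULL to use all surface residues (relative SASA above the cutoff).
#' @param config a `design_config`.
#' @param lib rotamer library.
#' @return a `design_run`: seed set, overlap edges, path tally, design table
#'   (one row per backbone) and the selected designs.
#' @export
run_design <- function(target, db, site = NULL, config = design_config(),
                       lib = default_rotamer_library()) {
  stage <- function(name, expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error"))
      stop(sprintf("design stage '%s' failed: %s", name,
                   attr(out, "condition")$message))
    out
  }
  clash <- clash_params(scale = config$clash_scale)
  if (is.null(site)) {
    sasa <- stage("surface", relative_sasa(target,
                                           surface_cutoff = config$surface_cutoff))
    site <- res_set(match(sasa$chain[sasa$surface],
                          vapply(target, `[[`, "", "chain_id")),
                    sasa$res[sasa$surface])
  }
  fp <- fragment_params(n_min_matches = config$n_min_matches,
                        rmsd_cutoff = config$rmsd_cutoff,
                        multi_segment = config$multi_segment)
  seeds <- stage("seeds", generate_seeds(target, site, db, fp,
                                         flank = config$flank, lib = lib,
                                         clash = clash))
  op <- overlap_params(window_len = config$window_len,
                       max_ca_dist = config$max_ca_dist,
                       max_frame_angle = config$max_frame_angle)
  overlaps <- stage("overlaps", find_overlaps(seeds, op))
  graph <- seed_graph(seeds, overlaps, op)
  sampled <- stage("paths", sample_paths(graph, n_accept = config$n_paths,
                                         min_length = config$min_length,
                                         target = target, clash = clash,
                                         rng_seed = config$rng_seed))
  backbones <- lapply(sampled$paths, `[[`, "backbone")
  if (!length(backbones)) {
    return(structure(list(seeds = seeds, overlaps = overlaps,
                          tally = sampled$tally, designs = NULL,
                          selected = NULL, config = config),
                     class = "design_run"))
  }
  contacts <- vapply(backbones, contacts_per_residue, 1, target = target,
                     lib = lib)
  scores <- vapply(seq_along(backbones), function(i) {
    if (contacts[i] == 0) return(NA_real_)
    term_interface_score(backbones[[i]], target, db, lib,
                         rmsd_cutoff = config$rmsd_cutoff,
                         ref_size = config$score_ref_size)
  }, 1)
  cl5 <- stage("cluster", cluster_backbones(backbones,
                                            config$cluster_threshold))
  cl20 <- cluster_backbones(backbones, config$cluster_threshold_coarse)
  records <- data.frame(
    design_id = sprintf("design%03d", seq_along(backbones)),
    length = vapply(backbones, nres, 1L),
    contacts_per_res = contacts,
    term_score = scores,
    cluster = cl5$assignment,
    cluster20 = cl20$assignment,
    stringsAsFactors = FALSE)
  records$term_score[is.na(records$term_score)] <- Inf
  records <- filter_and_select(records,
                               contacts_cutoff = config$contacts_cutoff,
                               score_cutoff = config$score_cutoff,
                               per_cluster = config$per_cluster)
  structure(list(seeds = seeds, overlaps = overlaps, tally = sampled$tally,
                 backbones = backbones, designs = records,
                 selected = records[records$selected, , drop = FALSE],
                 config = config),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat(sprintf("<design_run> %d seeds, %d overlaps, %d backbones, %d selected\n",
              length(x$seeds), nrow(x$overlaps),
              length(x$backbones %||% list()),
              sum(x$designs$selected %||% 0)))
  cat("path rejections:", paste(names(x$tally), x$tally, collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a design table as TSV
#' @param run a `design_run`.
#' @param path output path.
#' @export
write_design_table <- function(run, path) {
  utils::write.table(run$designs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
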