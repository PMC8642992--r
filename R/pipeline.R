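# End-to-end orchestration: simulate -> annotate -> quant -> screen ->
# coding -> design, with config validation and a machine-readable report.

run_config_defaults <- function() {
  c(unclass(sim_config()),
    list(pseudocount = 0.5, fc_threshold = 2, p_threshold = 0.05,
         recurrence_k = 3L, adjust = "none",
         min_len = 200L, max_len = 3000L, min_aa = 50L,
         start_window = 0.5, max_cycles = 3L,
         ires_window = 150L, ires_step = 10L, ires_threshold = 1.0,
         rnase_threshold = 0.5, tag_nt = flag_tag_3x(),
         promoter_width = 500L))
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or a YAML file path; fills defaults, rejects
#' unknown keys, type-checks every value and validates the embedded
#' simulation parameters (so e.g. a category mix not summing to 1 or
#' `n_pairs = 1` fails here, before any stage runs). All thresholds are
#' echoed into the run report for provenance.
#'
#' @param config Named list of overrides, or a YAML path, or NULL for
#'   defaults.
#' @return Normalized configuration list (class `circorf_config`).
#' @export
validate_config <- function(config = NULL) {
  defaults <- run_config_defaults()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (!is.null(config$category_mix))
      config$category_mix <- unlist(config$category_mix)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stopf("config must be a named list or a YAML path")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  char_keys <- c("adjust", "tag_nt")
  for (key in setdiff(names(defaults), c(char_keys, "category_mix"))) {
    if (!is.numeric(cfg[[key]]))
      stopf("config key '%s' must be numeric (got %s)", key,
            class(cfg[[key]])[1])
  }
  for (key in char_keys) {
    if (!is.character(cfg[[key]]))
      stopf("config key '%s' must be a string", key)
  }
  if (!is.numeric(cfg$category_mix))
    stopf("config key 'category_mix' must be numeric fractions")
  sim <- sim_config(seed = cfg$seed, n_contigs = cfg$n_contigs,
                    contig_length = cfg$contig_length,
                    n_genes = cfg$n_genes,
                    exons_per_gene = cfg$exons_per_gene,
                    category_mix = cfg$category_mix, n_circ = cfg$n_circ,
                    n_coding = cfg$n_coding, n_de_extra = cfg$n_de_extra,
                    n_pairs = cfg$n_pairs, planted_fc = cfg$planted_fc,
                    nb_dispersion = cfg$nb_dispersion,
                    read_length = cfg$read_length, depth = cfg$depth,
                    anchor = cfg$anchor)
  cfg$sim <- sim
  class(cfg) <- "circorf_config"
  cfg
}

#' Run the whole discovery pipeline on synthetic data
#'
#' Executes simulate -> annotate -> quant -> screen -> coding -> design,
#' writing every stage's outputs under `outdir` (subdirectories `genome/`,
#' `catalog/`, `quant/`, `screen/`, `coding/`, `design/`, `report/`).
#' Rerunning with the same configuration reproduces the deterministic
#' outputs byte for byte. Returns the run report: the category summary,
#' the discovery funnel (total -> DE -> recurrence -> length -> ORF ->
#' ORF position -> IRES = final candidates), candidate and design tables,
#' and the full configuration echo.
#'
#' @param config Configuration (list/YAML path/NULL), see
#'   [validate_config()].
#' @param outdir Output directory (created if needed).
#' @return A `circorf_report` list.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("circorf_run_")) {
  cfg <- if (inherits(config, "circorf_config")) config
         else validate_config(config)
  sim <- cfg$sim
  dirs <- file.path(outdir, c("genome", "catalog", "quant", "screen",
                              "coding", "design", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[stage] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  genome <- generate_genome(sim)
  plants <- plant_circrnas(genome, sim)
  write_genome_bundle(genome, file.path(outdir, "genome", "genome.fa"),
                      file.path(outdir, "genome", "annotation.gff3"))
  write_bsj_bed(plants$bsj, file.path(outdir, "catalog", "bsj.bed"))
  write_tsv(plants$truth, file.path(outdir, "genome", "truth.tsv"))
  toc(t0, "simulate")

  t0 <- tic()
  catalog <- annotate_bsj(plants$bsj, genome)
  catalog_summary <- summarize_catalog(catalog)
  write_tsv(catalog[, setdiff(names(catalog), "blocks")],
            file.path(outdir, "catalog", "catalog.tsv"))
  write_catalog_fasta(catalog, file.path(outdir, "catalog", "circles.fa"))
  toc(t0, "annotate")

  t0 <- tic()
  counts <- simulate_counts(plants$truth, sim)
  tpm <- tpm_normalize(counts$circ, counts$lengths)
  shared <- combined_circ_linear_tpm(counts)
  ratios <- circ_linear_ratio(shared$circ_tpm, shared$linear_tpm)
  reads <- simulate_junction_reads(catalog, genome, plants$truth, sim)
  write_fastq(reads$untreated, file.path(outdir, "quant",
                                         "reads_untreated.fastq"))
  write_fastq(reads$treated, file.path(outdir, "quant",
                                       "reads_rnaser.fastq"))
  fastq_counts <- count_bsj_reads(reads$untreated, catalog,
                                  anchor = sim$anchor)
  fastq_counts_treated <- count_bsj_reads(reads$treated, catalog,
                                          anchor = sim$anchor)
  rnase <- rnase_r_resistance(fastq_counts, fastq_counts_treated,
                              threshold = cfg$rnase_threshold)
  write_matrix_tsv(counts$circ, file.path(outdir, "quant",
                                          "counts_circ.tsv"), "circ_id")
  write_matrix_tsv(counts$linear, file.path(outdir, "quant",
                                            "counts_linear.tsv"), "circ_id")
  write_matrix_tsv(tpm, file.path(outdir, "quant", "tpm_circ.tsv"),
                   "circ_id")
  write_matrix_tsv(ratios, file.path(outdir, "quant",
                                     "circ_linear_ratio.tsv"), "circ_id")
  write_tsv(counts$design, file.path(outdir, "quant", "design.tsv"))
  write_tsv(rnase, file.path(outdir, "quant", "rnase_r.tsv"))
  toc(t0, "quant")

  t0 <- tic()
  screen <- screen_circrnas(tpm, counts$design,
                            pseudocount = cfg$pseudocount,
                            fc_threshold = cfg$fc_threshold,
                            p_threshold = cfg$p_threshold,
                            k = cfg$recurrence_k,
                            adjust = if (cfg$adjust == "BH") "BH"
                                     else "none")
  write_tsv(screen, file.path(outdir, "screen", "de_results.tsv"))
  toc(t0, "screen")

  t0 <- tic()
  orfs <- find_catalog_orfs(catalog, max_cycles = cfg$max_cycles)
  ires <- lapply(seq_len(nrow(catalog)), function(i)
    suppressWarnings(  # window is clipped for circles below window size
      scan_ires(catalog$sequence[i], window = cfg$ires_window,
                step = cfg$ires_step, threshold = cfg$ires_threshold)))
  names(ires) <- catalog$circ_id
  candidates <- rank_candidates(catalog, screen, orfs, ires,
                                min_len = cfg$min_len,
                                max_len = cfg$max_len,
                                min_aa = cfg$min_aa,
                                start_window = cfg$start_window)
  write_tsv(orfs, file.path(outdir, "coding", "orfs.tsv"))
  ires_df <- do.call(rbind, lapply(names(ires), function(id) {
    h <- ires[[id]]
    if (nrow(h)) cbind(circ_id = id, h, stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(ires_df))
    ires_df <- data.frame(circ_id = character(0), start = integer(0),
                          end = integer(0), score = numeric(0),
                          span = integer(0))
  write_tsv(ires_df, file.path(outdir, "coding", "ires.tsv"))
  write_tsv(candidates, file.path(outdir, "coding", "candidates.tsv"))
  toc(t0, "coding")

  t0 <- tic()
  finals <- candidates[candidates$passes_all, , drop = FALSE]
  finals <- finals[order(finals$rank), , drop = FALSE]
  designs <- design_candidates(finals, catalog, genome, cfg)
  if (nrow(designs$table))
    write_tsv(designs$table, file.path(outdir, "design", "designs.tsv"))
  if (length(designs$constructs)) {
    cons <- Biostrings::DNAStringSet(designs$constructs)
    Biostrings::writeXStringSet(cons, file.path(outdir, "design",
                                                "constructs.fa"))
  }
  toc(t0, "design")

  funnel <- pipeline_funnel(candidates, screen)
  report <- structure(list(
    seed = sim$seed, config = cfg, timings = timings,
    category_summary = catalog_summary, funnel = funnel,
    candidates = candidates, final_ids = finals$circ_id,
    designs = designs$table, truth = plants$truth,
    outdir = outdir), class = "circorf_report")
  write_tsv(data.frame(stage = names(funnel), count = as.integer(funnel)),
            file.path(outdir, "report", "funnel.tsv"))
  write_report_summary(report, file.path(outdir, "report",
                                         "run_summary.txt"))
  write_tsv(data.frame(stage = names(timings),
                       seconds = round(unname(timings), 2)),
            file.path(outdir, "report", "timings.tsv"))
  report
}

pipeline_funnel <- function(candidates, screen) {
  si <- match(candidates$circ_id, screen$circ_id)
  de <- screen$passes_de[si]
  rec <- de & screen$passes_recurrence[si]
  len <- rec & candidates$pass_length
  orf <- len & candidates$pass_orf
  pos <- orf & candidates$pass_orf_position
  ires <- pos & candidates$pass_ires
  c(total = nrow(candidates), de_pass = sum(de),
    recurrence_pass = sum(rec), length_pass = sum(len),
    orf_pass = sum(orf), orf_position_pass = sum(pos),
    final = sum(ires))
}

# junction-specific validation designs for the final candidates
design_candidates <- function(finals, catalog, genome, cfg) {
  rows <- list(); constructs <- character(0)
  for (i in seq_len(nrow(finals))) {
    id <- finals$circ_id[i]
    cat_row <- catalog[catalog$circ_id == id, ]
    seqc <- cat_row$sequence; L <- nchar(seqc)
    orf <- list(start = finals$orf_start[i], nt_length = finals$orf_nt[i],
                stop_pos = (finals$orf_start[i] + finals$orf_nt[i] - 3L)
                  %% L,
                rolling = FALSE, protein = finals$orf_protein[i])
    entry <- list(circ_id = id, rank = finals$rank[i],
                  orf_aa = finals$orf_aa[i])
    tagged <- tryCatch(tag_orf(seqc, orf, cfg$tag_nt),
                       error = function(e) NULL)
    mutant <- tryCatch(suppressWarnings(
      mutate_start(seqc, orf, max_cycles = cfg$max_cycles)),
      error = function(e) NULL)
    primers <- tryCatch(design_divergent_primers(seqc),
                        error = function(e) NULL)
    sirna <- paste0(substr(seqc, L - 9L, L), substr(seqc, 1L, 9L))
    tx <- if (!is.na(cat_row$gene_id))
      transcript_sequence(genome, cat_row$gene_id) else NULL
    si_check <- check_sirna_junction(sirna, seqc, tx)
    parent <- if (!is.na(cat_row$gene_id))
      parental_protein(genome, cat_row$gene_id) else NA_character_
    pep <- if (!is.na(parent) && nzchar(finals$orf_protein[i]))
      junction_peptide(finals$orf_protein[i], parent) else NULL
    promoter <- candidate_promoter(genome, cat_row$gene_id,
                                   cfg$promoter_width)
    tcf <- if (!is.null(promoter)) scan_tcf_sites(promoter) else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      circ_id = id, rank = finals$rank[i], orf_aa = finals$orf_aa[i],
      tagged_protein = if (!is.null(tagged)) tagged$expected_protein
                       else NA_character_,
      junction_kmer = junction_kmer(seqc),
      primer_forward = if (!is.null(primers)) primers$forward
                       else NA_character_,
      primer_reverse = if (!is.null(primers)) primers$reverse
                       else NA_character_,
      amplicon_length = if (!is.null(primers)) primers$amplicon_length
                        else NA_integer_,
      sirna = sirna,
      sirna_junction = si_check$junction_overlap,
      sirna_offtarget = si_check$linear_offtarget,
      novel_suffix = if (!is.null(pep)) pep$novel_suffix
                     else NA_character_,
      n_distinguishing_peptides = if (!is.null(pep))
        nrow(pep$distinguishing) else NA_integer_,
      tcf_sites_promoter = if (!is.null(tcf)) nrow(tcf) else NA_integer_,
      stringsAsFactors = FALSE)
    if (!is.null(tagged))
      constructs[sprintf("%s_tagged", id)] <- tagged$sequence
    if (!is.null(mutant))
      constructs[sprintf("%s_start_mutant", id)] <- mutant$sequence
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(circ_id = character(0))
  list(table = table, constructs = constructs)
}

# promoter region: `width` nt immediately upstream of the gene TSS
# (strand-aware), clipped to the contig
candidate_promoter <- function(genome, gene_id, width = 500L) {
  if (is.na(gene_id)) return(NULL)
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  ctg <- as.character(genome$contigs[[g$contig]])
  if (g$strand == "+") {
    from <- max(1L, g$start - width); to <- g$start - 1L
    if (to < from) return(NULL)
    substr(ctg, from, to)
  } else {
    from <- g$end + 1L; to <- min(nchar(ctg), g$end + width)
    if (to < from) return(NULL)
    revcomp(substr(ctg, from, to))
  }
}

write_report_summary <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("circorf run summary")
  w("seed: %d", report$seed)
  w("")
  w("category counts:")
  cs <- report$category_summary$categories
  for (i in seq_len(nrow(cs)))
    w("  %-18s %5d  (%d%%)", cs$category[i], cs$count[i], cs$percent[i])
  w("")
  w("discovery funnel:")
  for (nm in names(report$funnel))
    w("  %-18s %5d", nm, report$funnel[[nm]])
  w("")
  w("final candidates: %s",
    if (length(report$final_ids)) paste(report$final_ids, collapse = ", ")
    else "(none)")
  w("")
  w("thresholds: fc>%g p<%g recurrence>=%d length[%d,%d] min_aa=%d start_window=%g ires_threshold=%g",
    report$config$fc_threshold, report$config$p_threshold,
    report$config$recurrence_k, report$config$min_len,
    report$config$max_len, report$config$min_aa,
    report$config$start_window, report$config$ires_threshold)
}

#' @export
print.circorf_report <- function(x, ...) {
  cat("circorf pipeline report\n")
  cat(sprintf("  seed %d; outputs under %s\n", x$seed, x$outdir))
  cat("  funnel: ", paste(sprintf("%s=%d", names(x$funnel),
                                  as.integer(x$funnel)),
                          collapse = " -> "), "\n")
  cat(sprintf("  final candidates: %s\n",
              if (length(x$final_ids)) paste(x$final_ids, collapse = ", ")
              else "(none)"))
  invisible(x)
}
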