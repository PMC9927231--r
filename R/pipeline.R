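## End-to-end orchestration: compare -> diagnostic loci -> heteroplasmy,
## plus structure, SSR, diversity and tree stages, driven by one
## declarative config. Outputs are plain TSV/newick/YAML and are
## byte-identical when re-run with the same config and seed (no
## timestamps are written).

pipeline_defaults <- function() {
  list(out_dir = "plastotyper_out", seed = 1L,
       window = 1200L, step = 400L, anchor_k = 31L,
       ssr = list(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L), compound_gap = 100L),
       het = list(min_phred = 20, het_cutoff = 0.02, numt_ratio = 3.0,
                  consistency = 0.9),
       mask = NULL, nuclear_depth = NA, simulate = NULL,
       ref = NULL, query = NULL, basecounts = NULL, alignment = NULL,
       outgroup = NULL)
}

read_genome_auto <- function(path) {
  if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
    return(read_genbank(path))
  seqs <- read_fasta(path)
  plastome(names(seqs)[1L], seqs[[1L]])
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full comparison pipeline
#'
#' Stages: quadripartite structure and GC for both genomes; anchor
#' alignment, variant calling with annotation, inversion detection and
#' diagnostic-locus derivation; SSR scan of the reference; sliding-window
#' diversity and an NJ tree when an alignment is available; heteroplasmy
#' quantification when a base-count profile is available. Writes
#' `structure.tsv`, `variants.tsv`, `inversions.tsv`, `diagnostic_loci.tsv`,
#' `ssr.tsv`, and as applicable `diversity.tsv`, `tree.nwk`,
#' `heteroplasmy.tsv`, plus the fully-resolved `run_config.yaml` and a
#' `log.txt` with package version, seed and parameter echo. Any stage
#' error aborts the run.
#'
#' @param config A list or path to a YAML file. Recognized fields:
#'   `ref`/`query` (GenBank or FASTA paths), `basecounts` (TSV path),
#'   `alignment` (FASTA path of aligned samples), `nuclear_depth`, `mask`
#'   (c(start, end) interval excluded from diversity), `window`, `step`,
#'   `anchor_k`, `ssr$min_repeats`, `ssr$compound_gap`, `het$*`,
#'   `outgroup`, `seed`, `out_dir`, and `simulate` (a list of
#'   [simulation_config()] overrides; when present the inputs are
#'   generated and also written under `out_dir/inputs/`).
#' @param out_dir Output directory (overrides the config field).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("plastotyper %s", as.character(utils::packageVersion("plastotyper"))),
                 R.version.string,
                 sprintf("seed: %d", as.integer(cfg$seed)))
  results <- list(config = cfg)

  aln <- NULL; profile <- NULL; loci_from_sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- as.integer(cfg$seed)
    scfg <- do.call(simulation_config, sim_args[names(sim_args) %in%
                                                  names(formals(simulation_config))])
    pair <- make_cytotype_pair(scfg)
    pop <- simulate_population(pair)
    profile <- simulate_basecounts(pair$truth$loci, scfg$mixture_fraction, scfg,
                                   sample_id = "sim01")
    ref <- pair$type1; query <- pair$type2
    aln <- pop$alignment
    loci_from_sim <- pair$truth$loci
    inp <- file.path(cfg$out_dir, "inputs")
    dir.create(inp, showWarnings = FALSE)
    write_genbank(ref, file.path(inp, "type1.gb"))
    write_genbank(query, file.path(inp, "type2.gb"))
    write_fasta(aln$seqs, file.path(inp, "population_alignment.fasta"))
    write_basecounts(profile, file.path(inp, "basecounts.tsv"))
    jsonlite::write_json(list(variants = as.data.frame(pair$truth$variants),
                              inversion = pair$truth$inversion),
                         file.path(inp, "truth.json"))
    results$pair <- pair; results$population <- pop
    cfg$nuclear_depth <- scfg$nuclear_depth
    if (is.null(cfg$mask) && !is.null(pair$truth$inversion))
      cfg$mask <- pop$alignment$excluded
    log_lines <- c(log_lines, "inputs: simulated")
  } else {
    if (is.null(cfg$ref) || is.null(cfg$query))
      stop("config must provide 'ref' and 'query' genomes (or a 'simulate' block)")
    ref <- read_genome_auto(cfg$ref)
    query <- read_genome_auto(cfg$query)
    if (!is.null(cfg$alignment)) {
      seqs <- read_fasta(cfg$alignment)
      if (length(seqs) == 0L) stop("empty sample list in alignment ", cfg$alignment)
      aln <- alignment_matrix(seqs, excluded = cfg$mask)
    }
    if (!is.null(cfg$basecounts))
      profile <- read_basecounts(cfg$basecounts, nuclear_depth = cfg$nuclear_depth)
  }

  ## structure stage
  st <- lapply(list(ref, query), function(g)
    list(id = g$id, qs = detect_quadripartite(g), gc = gc_percent(g)))
  st_df <- do.call(rbind, lapply(st, function(x) {
    found <- isTRUE(x$qs$found)
    data.frame(genome = x$id, length = NA_integer_,
               lsc = if (found) x$qs$lengths[["lsc"]] else NA_integer_,
               ssc = if (found) x$qs$lengths[["ssc"]] else NA_integer_,
               ir = if (found) x$qs$lengths[["ir"]] else NA_integer_,
               gc_percent = x$gc)
  }))
  st_df$length <- c(length(ref), length(query))
  write.table(st_df, file.path(cfg$out_dir, "structure.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$structure <- st_df

  ## compare stage
  chain <- anchor_align(ref, query, k = as.integer(cfg$anchor_k))
  variants <- call_variants(ref, query, chain = chain, annotate = TRUE)
  write_variant_table(variants, file.path(cfg$out_dir, "variants.tsv"))
  inv <- detect_inversions(chain, ref = ref)
  write.table(inv, file.path(cfg$out_dir, "inversions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  loci <- if (!is.null(loci_from_sim)) loci_from_sim else {
    snps <- variants[variants$type == "SNP", , drop = FALSE]
    out <- data.frame(pos = snps$pos, allele_a = snps$ref, allele_b = snps$alt)
    class(out) <- c("diagnostic_locus_set", "data.frame")
    out
  }
  write.table(as.data.frame(loci), file.path(cfg$out_dir, "diagnostic_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$chain <- chain; results$variants <- variants; results$inversions <- inv
  results$loci <- loci

  ## ssr stage
  ssr_cfg <- ssr_config(cfg$ssr$min_repeats, cfg$ssr$compound_gap)
  ssrs <- classify_ssr_locations(find_ssrs(ref, ssr_cfg), ref)
  write.table(ssrs$table, file.path(cfg$out_dir, "ssr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$ssr <- ssrs

  ## diversity + tree stage
  if (!is.null(aln) && length(aln$ids) >= 2L) {
    prof_pi <- sliding_window_pi(aln, window = as.integer(cfg$window),
                                 step = as.integer(cfg$step))
    write.table(data.frame(start = prof_pi$start, end = prof_pi$end,
                           midpoint = prof_pi$midpoint, pi = prof_pi$pi),
                file.path(cfg$out_dir, "diversity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    dmat <- jc_distance_matrix(aln)
    nwk <- nj_tree(dmat, outgroup = cfg$outgroup)
    write_newick(nwk, file.path(cfg$out_dir, "tree.nwk"))
    results$diversity <- prof_pi; results$tree <- nwk
  }

  ## heteroplasmy stage
  if (!is.null(profile) && nrow(loci) >= 10L) {
    hcfg <- heteroplasmy_config(min_phred = cfg$het$min_phred,
                                het_cutoff = cfg$het$het_cutoff,
                                numt_ratio_threshold = cfg$het$numt_ratio,
                                consistency_fraction = cfg$het$consistency)
    filt <- filter_basecounts(profile, hcfg)
    call <- estimate_minor_fraction(filt, loci, hcfg)
    if (!is.na(call$nuclear_depth) && call$nuclear_depth > 0)
      call <- numt_guard(call, hcfg)
    het_df <- data.frame(sample = call$sample_id, major_type = call$major_type,
                         minor_fraction_median = call$minor_fraction,
                         minor_fraction_mean = call$minor_fraction_mean,
                         fraction_of_loci_supporting = call$fraction_of_loci_supporting,
                         minor_mean_depth = call$minor_mean_depth,
                         nuclear_depth = call$nuclear_depth,
                         n_usable_loci = call$n_usable_loci,
                         verdict = call$verdict)
    write.table(het_df, file.path(cfg$out_dir, "heteroplasmy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$heteroplasmy <- call
  }

  yaml::write_yaml(cfg, file.path(cfg$out_dir, "run_config.yaml"))
  log_lines <- c(log_lines,
                 sprintf("variants: %d", nrow(variants)),
                 sprintf("inversions: %d", nrow(inv)),
                 sprintf("ssrs: %d", nrow(ssrs$table)),
                 sprintf("parameters: window=%d step=%d k=%d",
                         as.integer(cfg$window), as.integer(cfg$step),
                         as.integer(cfg$anchor_k)))
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  invisible(results)
}
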