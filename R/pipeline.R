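#' Run configuration
#'
#' Collects every tunable parameter of an end-to-end run. For a file-based
#' run the paths must exist at validation time; for a synthetic demo run
#' the simulation config is used instead.
#'
#' @param genome_fa,genes_gff3 Input paths (NULL for a synthetic run).
#' @param rrna_bed,trna_bed,mirna_bed,repeats_bed Annotation BED paths.
#' @param libraries data.frame with columns `id`, `stage`, `argonaute`,
#'   `path` (NULL for a synthetic run).
#' @param params A [caller_params].
#' @param rpkm_target mRNA-target rpkm threshold (default 10, strict).
#' @param expressed_min Expression background cutoff (default 5 rpkm).
#' @param min_overlap_frac Classifier interval-overlap rule (default 0.5).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(genome_fa = NULL, genes_gff3 = NULL,
                       rrna_bed = NULL, trna_bed = NULL, mirna_bed = NULL,
                       repeats_bed = NULL, libraries = NULL,
                       params = caller_params(), rpkm_target = 10,
                       expressed_min = 5, min_overlap_frac = 0.5,
                       out_dir = "wagoseq_out", seed = 1L) {
  stopifnot(rpkm_target > 0, expressed_min > 0)
  paths <- c(genome_fa, genes_gff3, rrna_bed, trna_bed, mirna_bed,
             repeats_bed, if (!is.null(libraries)) libraries$path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("input path does not exist: %s", missing[1])
  structure(list(genome_fa = genome_fa, genes_gff3 = genes_gff3,
                 rrna_bed = rrna_bed, trna_bed = trna_bed,
                 mirna_bed = mirna_bed, repeats_bed = repeats_bed,
                 libraries = libraries, params = params,
                 rpkm_target = rpkm_target, expressed_min = expressed_min,
                 min_overlap_frac = min_overlap_frac,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' One-command synthetic demo run
#'
#' Generates a synthetic genome and a compact stage series, places the
#' reads, calls WAGO-repeat loci from the WAGO-class libraries, classifies
#' every library, calls mRNA targets, and writes the comparative
#' summaries, a BED of called loci, TSV tables and a run manifest with
#' md5 checksums of every output. Reruns with the same seed are
#' byte-identical.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param depth Reads per library (default: simulation default).
#' @param archetypes Archetypes to simulate.
#' @param stages Stages to simulate (default M1-M7; add "M8" for the
#'   noise library).
#' @param sim_cfg Optional [sim_config] overriding seed/depth.
#' @return Invisibly, a list with the main result objects (`sim`, `loci`,
#'   `targets`, `profiles`, `plasticity`, `pca`, `manifest`).
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("wagoseq_demo_"),
                     depth = NULL,
                     archetypes = c("WAGO12_like", "NRDE3_like", "CSR1_like"),
                     stages = c("M2", "M6"), sim_cfg = NULL) {
  cfg <- sim_cfg %||% sim_config(seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logline <- function(...) message(sprintf(...))

  logline("[simulate] genome seed=%d", cfg$seed)
  sim <- generate_genome(cfg)
  libs <- stage_series(sim, archetypes = archetypes, stages = stages,
                       depth = depth, seed = cfg$seed)
  write_simulation(sim, libs, file.path(out_dir, "sim"))

  logline("[place] %d libraries, exact full-length matching", length(libs))
  index <- build_index(sim$genome, sim$models, tx_seqs = Biostrings::DNAStringSet(sim$tx_strings))
  placements <- lapply(libs, function(sl) place_reads(sl$library, index))
  tracks <- lapply(placements, coverage_track, genome = sim$genome,
                   norm_target = cfg$norm_target)

  logline("[call-repeats] norm_target=%g seed_fold=%g merge_dist=%g min_len=%g enr_fold=%g",
          cfg$norm_target, 20, 2000, 50, 10)
  params <- caller_params(norm_target = cfg$norm_target)
  wago_names <- grep("WAGO12_like|NRDE3_like", names(libs), value = TRUE)
  wago_names <- grep("M8", wago_names, value = TRUE, invert = TRUE)
  loci <- call_wago_repeats(tracks[wago_names], sim$annotations, sim$genome,
                            params, placements = placements[wago_names])
  write_bed(loci, file.path(out_dir, "wago_repeats.bed"))
  if (!is.null(attr(loci, "rpkm")))
    write.table(data.frame(locus = rownames(attr(loci, "rpkm")),
                           attr(loci, "rpkm")),
                file.path(out_dir, "wago_repeats_rpkm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  logline("[classify] nine-category cascade, overlap rule >= 50%% read length")
  labels <- lapply(placements, classify_reads, annotations = sim$annotations,
                   wago_repeats = sim$annotations$repeats)
  profiles <- lapply(names(libs), function(nm)
    category_profile(labels[[nm]], libs[[nm]]$library))
  names(profiles) <- names(libs)
  for (nm in names(libs)) {
    write.table(profiles[[nm]],
                file.path(out_dir, paste0("category_profile_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sp <- size_profile(libs[[nm]]$library)
    write.table(data.frame(length = rownames(sp), sp),
                file.path(out_dir, paste0("size_profile_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  logline("[call-targets] antisense rpkm > 10, expressed >= 5")
  rpkm <- antisense_rpkm_matrix(placements, sim$models)
  targets <- call_targets(rpkm, threshold = 10)
  write.table(data.frame(gene = rownames(rpkm), round(rpkm, 4)),
              file.path(out_dir, "antisense_rpkm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- expression_groups(sim$expression)
  write.table(data.frame(gene = names(groups), group = groups),
              file.path(out_dir, "expression_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  logline("[stats] z-scores, PCA, plasticity")
  pca <- if (ncol(rpkm) >= 3) pca_libraries(rpkm) else NULL
  if (!is.null(pca))
    write.table(data.frame(library = rownames(pca$coords),
                           round(pca$coords, 6)),
                file.path(out_dir, "pca_coords.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  nrde <- grep("NRDE3_like", names(profiles), value = TRUE)
  plast <- if (length(nrde) >= 2) {
    pl <- plasticity_summary(setNames(profiles[nrde],
                                      sub("_NRDE3_like$", "", nrde)))
    write.table(pl, file.path(out_dir, "plasticity_NRDE3_like.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pl
  } else NULL

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("manifest\\.tsv$", files)]
  manifest <- data.frame(
    file = substring(files, nchar(out_dir) + 2L),
    md5 = unname(tools::md5sum(files)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, libs = libs, placements = placements,
                 loci = loci, rpkm = rpkm, targets = targets,
                 profiles = profiles, plasticity = plast, pca = pca,
                 manifest = manifest, out_dir = out_dir))
}

#' Run the full pipeline on user-supplied files
#'
#' Reads the genome, gene models, annotation BEDs and the library
#' manifest from a [run_config], then places reads, calls WAGO-repeat
#' loci from the libraries whose `argonaute` label contains "WAGO" or
#' "NRDE", classifies all libraries and calls mRNA targets, writing the
#' same outputs as [run_demo()].
#'
#' @param config A [run_config] with file paths set.
#' @return Invisibly, a result list (see [run_demo()]).
#' @export
run_all <- function(config) {
  stopifnot(is(config, "run_config"))
  genome <- read_fasta_genome(config$genome_fa)
  models <- read_gff3_genes(config$genes_gff3, genome)
  ann <- annotation_bundle(
    genome, models,
    rRNA = if (!is.null(config$rrna_bed)) read_bed(config$rrna_bed, "rRNA")
           else GenomicRanges::GRanges(),
    tRNA = if (!is.null(config$trna_bed)) read_bed(config$trna_bed, "tRNA")
           else GenomicRanges::GRanges(),
    miRNA = if (!is.null(config$mirna_bed)) read_bed(config$mirna_bed, "miRNA")
            else GenomicRanges::GRanges(),
    repeats = if (!is.null(config$repeats_bed))
      read_bed(config$repeats_bed, "repeat") else GenomicRanges::GRanges())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- build_index(genome, models)
  libs <- lapply(seq_len(nrow(config$libraries)), function(i)
    read_small_rna_library(config$libraries$path[i],
                           id = config$libraries$id[i],
                           stage = config$libraries$stage[i],
                           argonaute = config$libraries$argonaute[i]))
  names(libs) <- config$libraries$id
  placements <- lapply(libs, place_reads, index = index)
  tracks <- lapply(placements, coverage_track, genome = genome,
                   norm_target = config$params$norm_target)
  wago <- grepl("WAGO|NRDE", config$libraries$argonaute, ignore.case = TRUE)
  loci <- if (any(wago))
    call_wago_repeats(tracks[wago], ann, genome, config$params,
                      placements = placements[wago])
  else GenomicRanges::GRanges()
  write_bed(loci, file.path(config$out_dir, "wago_repeats.bed"))
  labels <- lapply(placements, classify_reads, annotations = ann,
                   wago_repeats = if (length(loci)) loci else ann$repeats,
                   min_overlap_frac = config$min_overlap_frac)
  profiles <- lapply(names(libs), function(nm) {
    pr <- category_profile(labels[[nm]], libs[[nm]])
    write.table(pr, file.path(config$out_dir,
                              paste0("category_profile_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pr
  })
  names(profiles) <- names(libs)
  rpkm <- antisense_rpkm_matrix(placements, models)
  targets <- call_targets(rpkm, threshold = config$rpkm_target)
  write.table(data.frame(gene = rownames(rpkm), round(rpkm, 4)),
              file.path(config$out_dir, "antisense_rpkm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = genome, models = models, annotations = ann,
                 placements = placements, loci = loci, rpkm = rpkm,
                 targets = targets, profiles = profiles))
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (paths, thresholds, caller parameters under `params`, and a `libraries`
#' list of id/stage/argonaute/path records). Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A validated [run_config].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the yaml package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p
                         else file.path(base, p)
  libs <- NULL
  if (!is.null(y$libraries)) {
    libs <- do.call(rbind, lapply(y$libraries, function(l)
      data.frame(id = l$id, stage = l$stage %||% NA_character_,
                 argonaute = l$argonaute %||% NA_character_,
                 path = resolve(l$path))))
  }
  params <- do.call(caller_params, y$params %||% list())
  run_config(genome_fa = resolve(y$genome_fa),
             genes_gff3 = resolve(y$genes_gff3),
             rrna_bed = resolve(y$rrna_bed),
             trna_bed = resolve(y$trna_bed),
             mirna_bed = resolve(y$mirna_bed),
             repeats_bed = resolve(y$repeats_bed),
             libraries = libs, params = params,
             rpkm_target = y$rpkm_target %||% 10,
             expressed_min = y$expressed_min %||% 5,
             min_overlap_frac = y$min_overlap_frac %||% 0.5,
             out_dir = y$out_dir %||% "wagoseq_out",
             seed = y$seed %||% 1L)
}
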