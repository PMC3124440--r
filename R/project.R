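default_project_config <- function(name, template = c("standard", "simulation")) {
  template <- match.arg(template)
  cfg <- list(
    project = list(name = name),
    inputs = list(
      reference = "reference.fasta",
      reads_short = "reads_short.fastq",
      reads_long = "reads_long.fastq",
      alignments = "alignments.sam",
      vcf = NULL,
      gff = "annotations.gff3",
      similarity = "similarity.tsv",
      enzymes = "enzymes.tsv"),
    cleaning = list(
      quality_threshold = 20,
      mode = "running_sum",
      min_len_short = 40,
      min_len_long = 100,
      adaptors = list(),
      max_mismatch_rate = 0.1),
    calling = list(
      min_map_qual = 15,
      min_allele_qual = 20),
    filters = list(
      apply = as.list(filter_names),
      maf_max = 0.80,
      hvr_max_pct = 4,
      i30_min_dist = 30,
      cl_min_dist = 30,
      cs_min_dist = 60,
      gf_max = 0.67,
      vk_kind = "any",
      maf_pool = list(),
      gf_libraries = list(),
      flank_len = 60),
    sets = list(
      po_min_accessions = 6,
      po_maf_max = 0.67,
      polymorphic_call_max_freq = 0.95),
    log_level = "info")
  if (template == "simulation") {
    cfg$simulation <- list(
      n_unigenes = 20, unigene_len_min = 900, unigene_len_max = 1100,
      n_accessions = 8, variant_rate = 0.01, indel_fraction = 0.1,
      reads_per_unigene_short = 400, reads_per_unigene_long = 13,
      read_len_short = 75, read_len_long = 400,
      error_rate = 0.005, adaptor_rate = 0,
      lowmapq_fraction = 0.1, intron_rate = 0.5,
      similarity_fraction = 0.2, seed = 42)
  }
  cfg
}

config_key_whitelist <- function() {
  list(project = c("name"),
       inputs = c("reference", "reads_short", "reads_long", "alignments",
                  "vcf", "gff", "similarity", "enzymes"),
       cleaning = c("quality_threshold", "mode", "min_len_short",
                    "min_len_long", "adaptors", "max_mismatch_rate"),
       calling = c("min_map_qual", "min_allele_qual"),
       filters = c("apply", "maf_max", "hvr_max_pct", "i30_min_dist",
                   "cl_min_dist", "cs_min_dist", "gf_max", "vk_kind",
                   "maf_pool", "gf_libraries", "flank_len"),
       sets = c("po_min_accessions", "po_maf_max",
                "polymorphic_call_max_freq"),
       simulation = c("n_unigenes", "unigene_len_min", "unigene_len_max",
                      "n_accessions", "variant_rate", "indel_fraction",
                      "reads_per_unigene_short", "reads_per_unigene_long",
                      "read_len_short", "read_len_long", "error_rate",
                      "adaptor_rate", "lowmapq_fraction", "intron_rate",
                      "similarity_fraction", "seed"),
       log_level = NULL)
}

validate_project_config <- function(cfg) {
  wl <- config_key_whitelist()
  unknown_sections <- setdiff(names(cfg), names(wl))
  if (length(unknown_sections)) {
    abort_config("unknown config section(s): ",
                 paste(unknown_sections, collapse = ", "))
  }
  for (sec in names(cfg)) {
    if (is.null(wl[[sec]])) next
    unknown <- setdiff(names(cfg[[sec]]), wl[[sec]])
    if (length(unknown)) {
      abort_config("unknown key(s) in section '", sec, "': ",
                   paste(unknown, collapse = ", "))
    }
  }
  invisible(cfg)
}

#' Create a new analysis project
#'
#' Materializes a project directory containing a commented starting
#' configuration with all default thresholds (caller: mapping quality 15,
#' allele quality 20; filters: 0.80, 4, 30, 30, 60, 0.67). Fails, touching
#' nothing, if the directory already exists.
#'
#' @param name Project (directory) name.
#' @param path Parent directory.
#' @param template `"standard"`, or `"simulation"` to include a synthetic
#'   data section so `analyze(stage = "simulate")` can generate the inputs.
#' @return The project directory path, invisibly.
#' @export
create_project <- function(name, path = ".",
                           template = c("standard", "simulation")) {
  template <- match.arg(template)
  dir <- file.path(path, name)
  if (dir.exists(dir)) {
    abort_config("project directory already exists: ", dir)
  }
  dir.create(dir, recursive = TRUE)
  cfg <- default_project_config(name, template)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read and validate a project configuration
#'
#' @param project Project directory (containing `config.yaml`).
#' @return The configuration list, with defaults filled in for absent keys;
#'   unknown sections or keys are rejected.
#' @export
read_project_config <- function(project) {
  path <- file.path(project, "config.yaml")
  if (!file.exists(path)) {
    abort_missing_input("no config.yaml in ", project)
  }
  cfg <- yaml::read_yaml(path)
  validate_project_config(cfg)
  defaults <- default_project_config(cfg$project$name %||% basename(project),
                                     template = "standard")
  for (sec in names(defaults)) {
    if (is.null(cfg[[sec]])) {
      cfg[[sec]] <- defaults[[sec]]
    } else if (is.list(defaults[[sec]])) {
      for (k in names(defaults[[sec]])) {
        if (!k %in% names(cfg[[sec]])) cfg[[sec]][[k]] <- defaults[[sec]][[k]]
      }
    }
  }
  cfg
}

sim_config_from_project <- function(s) {
  simulation_config(
    n_unigenes = s$n_unigenes %||% 20,
    unigene_len_range = c(s$unigene_len_min %||% 900,
                          s$unigene_len_max %||% 1100),
    n_accessions = s$n_accessions %||% 8,
    variant_rate = s$variant_rate %||% 0.01,
    indel_fraction = s$indel_fraction %||% 0.1,
    reads_per_unigene = c(short = s$reads_per_unigene_short %||% 400,
                          long = s$reads_per_unigene_long %||% 13),
    read_len = c(short = s$read_len_short %||% 75,
                 long = s$read_len_long %||% 400),
    error_rate = s$error_rate %||% 0.005,
    adaptor_rate = s$adaptor_rate %||% 0,
    lowmapq_fraction = s$lowmapq_fraction %||% 0.1,
    intron_rate = s$intron_rate %||% 0.5,
    similarity_fraction = s$similarity_fraction %||% 0.2,
    seed = s$seed %||% 42)
}

project_input <- function(project, cfg, key, stage, producer = NULL) {
  rel <- cfg$inputs[[key]]
  if (is.null(rel)) {
    abort_missing_input("stage '", stage, "' needs input '", key,
                        "' but none is configured")
  }
  p <- if (startsWith(rel, "/")) rel else file.path(project, rel)
  if (!file.exists(p)) {
    hint <- if (!is.null(producer)) {
      paste0(" (produced by the '", producer, "' stage)")
    } else {
      ""
    }
    abort_missing_input("stage '", stage, "' is missing input file ", p, hint)
  }
  p
}

log_line <- function(project, ...) {
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...,
             collapse = ""),
      file = file.path(project, "project.log"), sep = "\n", append = TRUE)
}

stage_clean <- function(project, cfg) {
  cl <- cfg$cleaning
  outdir <- file.path(project, "output")
  dir.create(outdir, showWarnings = FALSE)
  produced <- character(0)
  for (platform in c("short", "long")) {
    rel <- cfg$inputs[[paste0("reads_", platform)]]
    if (is.null(rel)) next
    path <- if (startsWith(rel, "/")) rel else file.path(project, rel)
    if (!file.exists(path)) next
    reads <- read_fastq(path, platform = platform)
    min_len <- if (platform == "short") cl$min_len_short else cl$min_len_long
    res <- clean_reads(reads,
                       adaptors = unlist(cl$adaptors),
                       quality_threshold = cl$quality_threshold,
                       mode = cl$mode, min_len = min_len,
                       max_mismatch_rate = cl$max_mismatch_rate)
    out_fastq <- file.path(outdir, paste0("cleaned_", platform, ".fastq"))
    write_fastq(res$reads, out_fastq)
    write_stats_table(quality_profile(res$reads),
                      file.path(outdir, paste0("quality_profile_", platform,
                                               ".tsv")))
    write_stats_table(length_distribution(res$reads),
                      file.path(outdir, paste0("length_distribution_",
                                               platform, ".tsv")))
    rep_df <- data.frame(platform = platform,
                         metric = names(unclass(res$report)),
                         value = unlist(unclass(res$report)))
    rep_path <- file.path(outdir, paste0("cleaning_report_", platform, ".tsv"))
    utils::write.table(rep_df, rep_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_line(project, "clean[", platform, "]: ", res$report$reads_in,
             " reads in, ", res$report$reads_out, " out")
    produced <- c(produced, out_fastq)
  }
  if (!length(produced)) {
    abort_missing_input("stage 'clean' found no FASTQ inputs in ", project)
  }
  produced
}

stage_call <- function(project, cfg) {
  outdir <- file.path(project, "output")
  dir.create(outdir, showWarnings = FALSE)
  aln_path <- project_input(project, cfg, "alignments", "call")
  ref_path <- project_input(project, cfg, "reference", "call")
  reference <- Biostrings::readDNAStringSet(ref_path)
  aln <- read_alignments(aln_path)
  pileup <- build_pileups(aln, reference)
  ccfg <- caller_config(min_map_qual = cfg$calling$min_map_qual,
                        min_allele_qual = cfg$calling$min_allele_qual)
  snvs <- call_snvs(pileup, ccfg)
  vcf_path <- file.path(outdir, "snvs_raw.vcf")
  write_vcf(snvs, vcf_path)
  write_stats_table(coverage_distribution(pileup),
                    file.path(outdir, "coverage_distribution.tsv"))
  log_line(project, "call: ", length(snvs), " SNVs from ",
           nrow(aln$records), " alignments")
  vcf_path
}

stage_filter <- function(project, cfg) {
  outdir <- file.path(project, "output")
  dir.create(outdir, showWarnings = FALSE)
  vcf_in <- if (!is.null(cfg$inputs$vcf)) {
    project_input(project, cfg, "vcf", "filter")
  } else {
    p <- file.path(outdir, "snvs_raw.vcf")
    if (!file.exists(p)) {
      abort_missing_input("stage 'filter' is missing ", p,
                          " (produced by the 'call' stage)")
    }
    p
  }
  ref_path <- project_input(project, cfg, "reference", "filter")
  reference <- Biostrings::readDNAStringSet(ref_path)
  names(reference) <- sub("\\s.*$", "", names(reference))
  snvs <- read_vcf(vcf_in)
  attr(snvs, "reference") <- reference
  fl <- cfg$filters
  apply_list <- unlist(fl$apply)
  gff_path <- NULL
  sim_path <- NULL
  if ("I30" %in% apply_list) {
    gff_path <- project_input(project, cfg, "gff", "filter")
  }
  if ("UCR" %in% apply_list) {
    sim_path <- project_input(project, cfg, "similarity", "filter")
  }
  enzymes <- if ("CEF" %in% apply_list && !is.null(cfg$inputs$enzymes)) {
    enz_path <- if (startsWith(cfg$inputs$enzymes, "/")) {
      cfg$inputs$enzymes
    } else {
      file.path(project, cfg$inputs$enzymes)
    }
    if (file.exists(enz_path)) default_enzymes(enz_path) else default_enzymes()
  } else {
    default_enzymes()
  }
  fcfg <- filter_config(
    maf_max = fl$maf_max, hvr_max_pct = fl$hvr_max_pct,
    i30_min_dist = fl$i30_min_dist, cl_min_dist = fl$cl_min_dist,
    cs_min_dist = fl$cs_min_dist, gf_max = fl$gf_max, vk_kind = fl$vk_kind,
    maf_pool = unlist(fl$maf_pool) %||% character(0),
    gf_libraries = unlist(fl$gf_libraries) %||% character(0),
    enzymes = enzymes, flank_len = fl$flank_len)
  contexts <- build_contexts(reference, snvs, gff_path = gff_path,
                             similarity_path = sim_path)
  tagged <- apply_filters(snvs, contexts, fcfg, filters = apply_list)
  out_vcf <- file.path(outdir, "snvs_filtered.vcf")
  write_vcf(tagged, out_vcf, reference = reference)
  tags <- snv_tags(tagged)
  tag_df <- data.frame(snv = rownames(tags), tags, check.names = FALSE)
  utils::write.table(tag_df, file.path(outdir, "snv_tags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_line(project, "filter: tagged ", length(tagged), " SNVs with ",
           length(apply_list), " filters")
  out_vcf
}

stage_stats <- function(project, cfg) {
  outdir <- file.path(project, "output")
  dir.create(outdir, showWarnings = FALSE)
  vcf_path <- file.path(outdir, "snvs_filtered.vcf")
  if (!file.exists(vcf_path)) {
    vcf_path <- file.path(outdir, "snvs_raw.vcf")
  }
  if (!file.exists(vcf_path)) {
    abort_missing_input("stage 'stats' is missing ",
                        file.path(outdir, "snvs_filtered.vcf"),
                        " (produced by the 'filter' stage)")
  }
  snvs <- read_vcf(vcf_path)
  crit <- set_criteria(
    po_min_accessions = cfg$sets$po_min_accessions,
    po_maf_max = cfg$sets$po_maf_max,
    polymorphic_call_max_freq = cfg$sets$polymorphic_call_max_freq)
  tab <- snv_table(snvs, crit)
  tags <- snv_tags(snvs)
  if (all(c("MAF", "HVR") %in% colnames(tags))) {
    tab <- cbind(tab, marker_sets(tags))
  }
  out <- file.path(outdir, "snv_table.tsv")
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(project, "stats: summarized ", nrow(tab), " SNVs")
  out
}

stage_simulate <- function(project, cfg) {
  if (is.null(cfg$simulation)) {
    abort_config("project config has no 'simulation' section; ",
                 "create the project with template = \"simulation\"")
  }
  sim_cfg <- sim_config_from_project(cfg$simulation)
  simulate_project(sim_cfg, project)
  log_line(project, "simulate: generated project inputs (seed ",
           sim_cfg$seed, ")")
  invisible(project)
}

#' Run analysis stages on a project
#'
#' Stages run in the fixed order clean, call, filter, stats; each reads and
#' writes only standard-format files under the project directory, so any
#' stage is a valid entry point — e.g. `stage = "filter"` on a project that
#' provides a VCF but no FASTQ works. `stage = "all"` runs
#' clean→call→filter→stats; `"simulate"` generates the synthetic inputs
#' first (requires a `simulation` config section). Outputs are deterministic:
#' identical config, inputs and seed give byte-identical VCF and tag tables
#' regardless of `threads` (per-unigene work is merged in reference order).
#'
#' @param project Project directory created by [create_project()].
#' @param stage One of `"clean"`, `"call"`, `"filter"`, `"stats"`,
#'   `"simulate"`, `"all"`.
#' @param threads Accepted for interface compatibility; results are
#'   independent of its value.
#' @return Invisibly, the paths produced by the final stage run.
#' @export
analyze <- function(project,
                    stage = c("all", "clean", "call", "filter", "stats",
                              "simulate"),
                    threads = 1L) {
  stage <- match.arg(stage)
  stopifnot(threads >= 1L)
  cfg <- read_project_config(project)
  cfg_path <- file.path(project, "config.yaml")
  log_line(project, "analyze stage=", stage,
           " snvmine=", as.character(utils::packageVersion("snvmine")),
           " config_md5=", unname(tools::md5sum(cfg_path)))
  stages <- if (stage == "all") c("clean", "call", "filter", "stats") else stage
  res <- NULL
  for (s in stages) {
    res <- switch(s,
                  clean = stage_clean(project, cfg),
                  call = stage_call(project, cfg),
                  filter = stage_filter(project, cfg),
                  stats = stage_stats(project, cfg),
                  simulate = stage_simulate(project, cfg))
  }
  invisible(res)
}
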