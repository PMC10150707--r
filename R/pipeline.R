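# Recognized configuration keys (flat, namespaced). Unknown keys are
# rejected before any stage runs.
PIPELINE_KEYS <- c(
  "out_dir", "seed", "log_level", "stages",
  "input.counts", "input.sample_sheet", "input.fasta", "input.fastq_dir",
  "input.sites", "input.gtf", "input.cgi",
  "normalization.min_count", "normalization.min_samples",
  "normalization.prior_count", "normalization.libsize_adjust",
  "diff.contrast", "diff.pair_by", "diff.fc_thresh", "diff.p_thresh",
  "dhmr.k", "dhmr.max_span", "dhmr.direction",
  "cluster.p_thresh")

# Internal: flatten a nested list into namespaced keys.
flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]])))
      out <- c(out, flatten_config(x[[nm]], key))
    else out[[key]] <- x[[nm]]
  }
  out
}

#' Load and validate a pipeline configuration
#'
#' @param config named list or path to a YAML file; nested sections are
#'   flattened to namespaced keys (e.g. \code{normalization.min_count}).
#' @return validated flat configuration list with defaults filled in.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- flatten_config(config)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    hx_stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) hx_stop("configuration requires out_dir")
  if (is.null(cfg$seed)) hx_stop("configuration requires seed")
  defaults <- list("normalization.min_count" = 10,
                   "normalization.min_samples" = 3L,
                   "normalization.prior_count" = 0.5,
                   "normalization.libsize_adjust" = 1,
                   "diff.contrast" = "NSC:iPSC",
                   "diff.pair_by" = "subject",
                   "diff.fc_thresh" = 1, "diff.p_thresh" = 0.05,
                   "dhmr.k" = 9L, "dhmr.max_span" = 50000L,
                   "dhmr.direction" = "A_less",
                   "cluster.p_thresh" = 0.01)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

#' Validate pipeline input files and the sample sheet
#'
#' Checks that referenced paths exist and parse, that the sample sheet
#' carries the required columns (sample, subject, cell_type, group,
#' pair, age, sex), and that pairing is consistent (one sample per
#' subject and cell type).
#'
#' @param paths named character vector / list of input paths (any of
#'   counts, sample_sheet, fasta, sites, gtf, cgi).
#' @param sample_sheet data.frame, or NULL to read from
#'   \code{paths$sample_sheet}.
#' @return character vector of failures (empty when valid).
#' @export
validate_inputs <- function(paths = list(), sample_sheet = NULL) {
  failures <- character(0)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      failures <- c(failures, paste0("missing file for ", nm, ": ", p))
  }
  parse_try <- function(nm, fun) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) return(NULL)
    tryCatch({ fun(p); NULL },
             error = function(e) paste0("unparseable ", nm, ": ",
                                        conditionMessage(e)))
  }
  failures <- c(failures,
                parse_try("fasta", Biostrings::readDNAStringSet),
                parse_try("gtf", rtracklayer::import),
                parse_try("cgi", function(p)
                  rtracklayer::import(p, format = "BED")),
                parse_try("counts", read_counts))
  if (is.null(sample_sheet) && !is.null(paths$sample_sheet) &&
      file.exists(paths$sample_sheet))
    sample_sheet <- read_tsv(paths$sample_sheet)
  if (!is.null(sample_sheet)) {
    need <- c("sample", "subject", "cell_type", "group", "pair", "age",
              "sex")
    miss <- setdiff(need, colnames(sample_sheet))
    if (length(miss))
      failures <- c(failures, paste0("sample sheet missing column(s): ",
                                     paste(miss, collapse = ", ")))
    if (all(c("subject", "cell_type") %in% colnames(sample_sheet))) {
      dup <- duplicated(sample_sheet[, c("subject", "cell_type")])
      if (any(dup))
        failures <- c(failures,
                      paste0("subject with duplicate cell-type sample: ",
                             paste(unique(sample_sheet$subject[dup]),
                                   collapse = ", ")))
    }
    if ("sample" %in% colnames(sample_sheet) &&
        any(duplicated(sample_sheet$sample)))
      failures <- c(failures, "duplicate sample identifiers")
  }
  failures
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the stages in dependency order — digest, quant (or count
#' import), annotate, normalize, diff, dhmr, cluster — writing every
#' output under \code{out_dir} and recording a manifest (input hashes,
#' effective parameters, seed). Reruns with an identical configuration
#' are byte-identical for the deterministic stages.
#'
#' @param config named list or YAML path (see [load_config()]).
#' @return the manifest, invisibly a list with \code{outputs},
#'   \code{parameter_hash}, \code{seed}, \code{inputs}.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(cfg$seed))
  paths <- cfg[grep("^input\\.", names(cfg))]
  names(paths) <- sub("^input\\.", "", names(paths))
  fails <- validate_inputs(paths[setdiff(names(paths), "fastq_dir")])
  if (length(fails)) hx_stop("input validation failed:\n  ",
                             paste(fails, collapse = "\n  "))
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    outputs <<- c(outputs, p)
    p
  }
  log_msg <- function(...) {
    if (identical(cfg$log_level, "quiet")) return(invisible())
    message("[hydroxyscan] ", ...)
  }

  sheet <- read_tsv(paths$sample_sheet)

  # digest + quant, or direct count import
  if (!is.null(paths$fasta)) {
    genome <- Biostrings::readDNAStringSet(paths$fasta)
    sitemap <- find_ccgg_sites(genome, genome_id = basename(paths$fasta))
    write_site_map(sitemap, bed = emit("sites.bed"), tsv = emit("sites.tsv"))
    log_msg("digest: ", nrow(sitemap), " CCGG sites")
  } else sitemap <- NULL
  if (!is.null(paths$fastq_dir)) {
    if (is.null(sitemap)) hx_stop("quant stage requires input.fasta")
    fq <- list.files(paths$fastq_dir, "\\.fastq(\\.gz)?$",
                     full.names = TRUE)
    if (!length(fq)) hx_stop("no FASTQ files under ", paths$fastq_dir)
    assignments <- lapply(fq, function(f) {
      ft <- filter_and_trim(read_fastq(f))
      place_reads(ft$kept, sitemap, genome)$assignments
    })
    names(assignments) <- sub("\\.fastq(\\.gz)?$", "", basename(fq))
    counts <- count_sites(assignments, sitemap)
    write_counts(counts, emit("counts.tsv"))
    log_msg("quant: ", sum(counts$counts), " reads on sites")
  } else if (!is.null(paths$counts)) {
    counts <- read_counts(paths$counts)
    if (is.null(sitemap)) sitemap <- counts$sites
  } else hx_stop("missing upstream output for stage 'normalize': ",
                 "provide input.counts or input.fasta + input.fastq_dir")

  # annotate
  if (!is.null(paths$gtf) && !is.null(paths$cgi)) {
    gm <- read_gene_models(paths$gtf)
    ann <- annotate_sites(counts$sites, gm, paths$cgi)
    write_tsv(ann, emit("annotation.tsv"))
    log_msg("annotate: ", nrow(ann), " sites annotated")
  }

  # normalize
  norm <- normalize_pipeline(counts, sheet,
                             min_count = cfg$`normalization.min_count`,
                             min_samples = cfg$`normalization.min_samples`,
                             prior_count = cfg$`normalization.prior_count`,
                             libsize_adjust = cfg$`normalization.libsize_adjust`)
  write_tsv(data.frame(site = rownames(norm$logcpm), norm$logcpm,
                       check.names = FALSE), emit("logcpm.tsv"))
  log_msg("normalize: ", sum(norm$keep), " of ", length(norm$keep),
          " sites retained")

  # differential
  contrast <- strsplit(cfg$`diff.contrast`, ":", fixed = TRUE)[[1]]
  diff <- differential_sites(norm$logcpm, norm$sample_sheet, contrast,
                             pair_by = cfg$`diff.pair_by`,
                             fc_thresh = cfg$`diff.fc_thresh`,
                             p_thresh = cfg$`diff.p_thresh`)
  write_tsv(diff, emit("diff.tsv"))
  log_msg("diff: ", sum(diff$p_value < cfg$`diff.p_thresh`),
          " nominally significant sites")

  # dhmr
  scan <- dhmr_scan(diff, dhmr_params(k = cfg$`dhmr.k`,
                                      max_span = cfg$`dhmr.max_span`,
                                      direction = cfg$`dhmr.direction`))
  write_tsv(scan$loci, emit("dhmr.tsv"))
  log_msg("dhmr: ", nrow(scan$loci), " loci; Bonferroni bins ",
          scan$bonferroni$n_bins)

  # cluster
  cl <- tryCatch(cluster_top_sites(norm$logcpm, diff,
                                   cfg$`cluster.p_thresh`),
                 error = function(e) NULL)
  if (!is.null(cl)) {
    write_tsv(data.frame(site = rownames(cl$zscores), cl$zscores,
                         check.names = FALSE), emit("zscores.tsv"))
    write_tsv(data.frame(merge1 = cl$sample_tree$merge[, 1],
                         merge2 = cl$sample_tree$merge[, 2],
                         height = cl$sample_tree$height),
              emit("sample_tree.tsv"))
    writeLines(cl$sample_tree$labels[cl$sample_tree$order],
               emit("sample_order.txt"))
  }

  in_files <- unlist(paths[vapply(paths, function(p)
    is.character(p) && file.exists(p) && !dir.exists(p), logical(1))])
  manifest <- list(
    outputs = basename(outputs),
    inputs = as.list(tools::md5sum(in_files)),
    parameter_hash = config_hash(cfg),
    seed = cfg$seed)
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(manifest)
}

# Internal: md5 of the canonically serialized effective parameters.
config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vapply(names(cfg), function(k)
    paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ",")),
    character(1)), tmp)
  unname(tools::md5sum(tmp))
}
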