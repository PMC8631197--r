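#' Pipeline configuration
#'
#' Collects every tunable threshold of the end-to-end analysis with the
#' conventional ceRNA-inference values as defaults: DE at |log2FC| >= 1 and
#' adjusted p < 0.05 (`padj_cut = 0.1` is the common looser variant),
#' miRNA-target anti-correlation r < −0.9, sponge-mRNA co-expression
#' r > 0.8, correlation p < 0.05, at least 3 shared miRNAs, sponge-test
#' p < 0.05. Input is either a [sim_config()] (fixture mode) or a directory
#' laid out as by [write_fixture()].
#'
#' @param sim A [sim_config()] for fixture mode, or `NULL` when reading
#'   from `input_dir`.
#' @param input_dir Directory of input files (see [read_fixture()]).
#' @param gmt_path Optional GMT path; defaults to `genesets.gmt` in
#'   `input_dir` or the fixture GMT in fixture mode.
#' @param lfc_cut,padj_cut DE thresholds ([call_de()]).
#' @param r_max,r_min,p_max Correlation thresholds ([assemble_network()]).
#' @param min_shared_mirnas,p_hyper_cut Sponge-pair thresholds.
#' @param min_class,min_score Binding-evidence rule ([build_target_table()]).
#' @param weight,n_perm GSEA parameters.
#' @param rng_seed Seed for the permutation stages (and, in fixture mode,
#'   for the simulation unless the sim config sets its own).
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the full result bundle there.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            gmt_path = NULL,
                            lfc_cut = 1, padj_cut = 0.05,
                            r_max = -0.9, r_min = 0.8, p_max = 0.05,
                            min_shared_mirnas = 3, p_hyper_cut = 0.05,
                            min_class = "7mer-A1", min_score = NULL,
                            weight = 1, n_perm = 1000,
                            rng_seed = 1, out_dir = NULL) {
  cfg <- list(
    sim = sim, input_dir = input_dir, gmt_path = gmt_path,
    lfc_cut = lfc_cut, padj_cut = padj_cut, r_max = r_max, r_min = r_min,
    p_max = p_max, min_shared_mirnas = min_shared_mirnas,
    p_hyper_cut = p_hyper_cut, min_class = min_class, min_score = min_score,
    weight = weight, n_perm = n_perm, rng_seed = rng_seed, out_dir = out_dir
  )
  if (is.null(sim) && is.null(input_dir)) {
    abort("either a sim config or an input_dir is required")
  }
  if (lfc_cut < 0) abort("lfc_cut must be >= 0")
  if (padj_cut <= 0 || padj_cut > 1) abort("padj_cut must lie in (0, 1]")
  if (r_max >= 0 || r_max < -1) abort("r_max must lie in [-1, 0)")
  if (r_min <= 0 || r_min > 1) abort("r_min must lie in (0, 1]")
  if (p_max <= 0 || p_max > 1) abort("p_max must lie in (0, 1]")
  if (min_shared_mirnas < 1) abort("min_shared_mirnas must be >= 1")
  if (p_hyper_cut <= 0 || p_hyper_cut > 1) abort("p_hyper_cut must lie in (0, 1]")
  if (!min_class %in% SITE_CLASSES) abort("unknown min_class")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file holding the fields of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    raw$sim$n_features <- unlist(raw$sim$n_features)
    raw$sim$de_fraction <- unlist(raw$sim$de_fraction)
    raw$sim$nb_mean_range <- unlist(raw$sim$nb_mean_range)
    raw$sim <- do.call(sim_config, raw$sim)
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) {
    sim <- unclass(cfg$sim)
    # named vectors go out as YAML maps, not bare sequences
    for (f in c("n_features", "de_fraction")) sim[[f]] <- as.list(sim[[f]])
    cfg$sim <- sim
  }
  cfg <- purrr::discard(cfg, is.null)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

stage_log <- function(stage, n_in, n_out, t0) {
  message(sprintf("[%s] in=%d out=%d elapsed=%.2fs", stage, n_in, n_out,
                  as.numeric(Sys.time()) - t0))
}

#' Run the whole ceRNA pipeline
#'
#' Executes simulate (or load) -> normalize -> differential expression per
#' RNA class -> seed-site scan of DE miRNAs against DE targets -> lncRNA-
#' and circRNA-based network assembly -> hub-mRNA intersection ->
#' over-representation and GSEA enrichment, logging one line per stage to
#' stderr. With a fixed `rng_seed` the whole bundle, including the
#' permutation stages, is reproducible; when `out_dir` is set every result
#' is written there along with a manifest of file checksums and a
#' deterministic manifest hash.
#'
#' mRNA and lncRNA counts are reported as FPKM, miRNA as TPM, circRNA BSJ
#' counts as SRPBM. The Wald tests and the correlation filters run on
#' median-of-ratios-normalized counts per class (mapped-read-total factors
#' as fallback when no feature is positive everywhere): within-sample
#' totals such as TPM are compositional, and a handful of strongly
#' regulated features would otherwise distort every other feature's
#' correlations. Correlations use log2(normalized count + 1) across the
#' pooled samples of both groups.
#'
#' @param config A [pipeline_config()].
#' @return A `cerna_pipeline` bundle: `dataset`, `de` (per class), `expr`
#'   (log2 normalized matrix), `target_pairs`, `networks` (`$lncRNA`,
#'   `$circRNA`), `hub_mrnas`, `ora`, `gsea`, `summary`, `manifest`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$input_dir)) {
    dataset <- read_fixture(config$input_dir)
    gmt_path <- config$gmt_path %||% file.path(config$input_dir, "genesets.gmt")
    gmt <- if (file.exists(gmt_path)) read_gmt(gmt_path) else NULL
  } else {
    dataset <- simulate_experiment(config$sim)
    gmt <- NULL
    if (!is.null(config$gmt_path)) gmt <- read_gmt(config$gmt_path)
  }
  stage_log("input", sum(vapply(dataset$counts, nrow, integer(1))),
            nrow(dataset$samples), t0)

  # reporting-scale normalization per class
  t1 <- as.numeric(Sys.time())
  norm <- list(
    mRNA = fpkm(dataset$counts$mRNA),
    lncRNA = fpkm(dataset$counts$lncRNA),
    circRNA = srpbm(dataset$counts$circRNA, dataset$mapped_reads),
    miRNA = tpm(dataset$counts$miRNA)
  )
  # correlation/test scale: median-of-ratios normalized log2 counts. One
  # factor per sample, estimated from the pooled mRNA+lncRNA compartments:
  # within-sample totals (TPM and friends) are compositional, and the small
  # miRNA/circRNA classes can have most of their features perturbed, which
  # breaks a per-class median-of-ratios.
  mr <- dataset$mapped_reads
  sf_mapped <- mr / exp(mean(log(mr)))
  sf <- tryCatch(
    size_factors(bind_rows(dataset$counts$mRNA, dataset$counts$lncRNA)),
    error = function(e) sf_mapped
  )
  sfs <- purrr::map(dataset$counts, function(x) sf)
  expr <- do.call(rbind, purrr::map(dataset$counts, function(cts) {
    sweep(count_values(cts), 2, sf, "/")
  }))
  expr <- log2(expr + 1)
  stage_log("normalize", nrow(expr), nrow(expr), t1)

  # per-class differential expression
  t1 <- as.numeric(Sys.time())
  groups <- dataset$samples
  de <- purrr::imap(dataset$counts, function(cts, cl) {
    call_de(nb_wald_test(cts, groups, sf = sfs[[cl]]),
            lfc_cut = config$lfc_cut, padj_cut = config$padj_cut)
  })
  n_de <- sum(purrr::map_int(de, function(d) sum(d$direction != "ns")))
  stage_log("de", nrow(expr), n_de, t1)

  # binding evidence: DE miRNAs scanned against DE targets
  t1 <- as.numeric(Sys.time())
  de_ids <- purrr::map(de, function(d) d$feature_id[d$direction != "ns"])
  mirna_seqs <- dataset$sequences$mirna[
    intersect(de_ids$miRNA, names(dataset$sequences$mirna))]
  target_ids <- intersect(
    c(de_ids$mRNA, de_ids$lncRNA, de_ids$circRNA),
    names(dataset$sequences$target)
  )
  target_pairs <- build_target_table(
    mirna_seqs, dataset$sequences$target[target_ids],
    min_class = config$min_class, min_score = config$min_score
  )
  stage_log("scan", length(mirna_seqs) * length(target_ids),
            nrow(target_pairs), t1)

  # networks
  t1 <- as.numeric(Sys.time())
  networks <- purrr::map(
    setNames(c("lncRNA", "circRNA"), c("lncRNA", "circRNA")),
    function(cl) {
      assemble_network(
        de, target_pairs, expr, ce_class = cl,
        r_max = config$r_max, r_min = config$r_min, p_max = config$p_max,
        min_shared_mirnas = config$min_shared_mirnas,
        p_hyper_cut = config$p_hyper_cut
      )
    }
  )
  hub_mrnas <- intersect_hub_mrnas(networks$lncRNA, networks$circRNA)
  stage_log("cerna", nrow(target_pairs),
            sum(purrr::map_int(networks, function(n) nrow(n$edges))), t1)

  # enrichment over the supplied gene sets
  t1 <- as.numeric(Sys.time())
  ora <- NULL
  gsea <- NULL
  if (!is.null(gmt) && nrow(gmt) > 0) {
    study <- de_ids$mRNA
    population <- de$mRNA$feature_id
    if (length(study) > 0) ora <- ora_batch(study, population, gmt)
    ranked <- rank_features(de$mRNA)
    gsea <- tryCatch(
      gsea_batch(ranked, gmt, n_perm = config$n_perm,
                 seed = config$rng_seed, weight = config$weight),
      error = function(e) NULL
    )
  }
  stage_log("enrich", if (is.null(gmt)) 0L else nrow(gmt),
            if (is.null(gsea)) 0L else nrow(gsea), t1)

  summary <- list(
    de = purrr::imap(de, function(d, cl) glance(d)),
    networks = purrr::map(networks, network_summary),
    n_hub_mrnas = length(hub_mrnas)
  )
  bundle <- structure(list(
    dataset = dataset, de = de, expr = expr, target_pairs = target_pairs,
    networks = networks, hub_mrnas = hub_mrnas, ora = ora, gsea = gsea,
    summary = summary, manifest = NULL, config = config
  ), class = "cerna_pipeline")

  if (!is.null(config$out_dir)) {
    bundle$manifest <- write_bundle(bundle, config$out_dir)
  }
  stage_log("done", nrow(expr),
            summary$networks$lncRNA$n_edges + summary$networks$circRNA$n_edges,
            t0)
  bundle
}

# Write every result table plus a manifest whose hash covers the config and
# the checksums of all deterministic outputs.
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cl in names(bundle$de)) {
    f <- file.path(dir, paste0("de_", cl, ".tsv"))
    readr::write_tsv(as_tibble(bundle$de[[cl]]), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "target_pairs.tsv")
  readr::write_tsv(as_tibble(bundle$target_pairs), f)
  files <- c(files, f)
  for (cl in names(bundle$networks)) {
    files <- c(files, export_network(bundle$networks[[cl]], dir,
                                     name = paste0("cerna_", cl)))
  }
  readr::write_lines(bundle$hub_mrnas, file.path(dir, "hub_mrnas.txt"))
  files <- c(files, file.path(dir, "hub_mrnas.txt"))
  if (!is.null(bundle$ora)) {
    f <- file.path(dir, "ora.tsv")
    readr::write_tsv(bundle$ora, f)
    files <- c(files, f)
  }
  if (!is.null(bundle$gsea)) {
    f <- file.path(dir, "gsea.tsv")
    readr::write_tsv(bundle$gsea, f)
    files <- c(files, f)
  }
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(dir, "summary.json"))

  cfg <- unclass(bundle$config)
  cfg$out_dir <- NULL
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  cfg_json <- jsonlite::toJSON(purrr::discard(cfg, is.null),
                               auto_unbox = TRUE, digits = NA)
  md5 <- tools::md5sum(files)
  hash_src <- paste(c(as.character(cfg_json), paste(basename(files), md5)),
                    collapse = "\n")
  tf <- tempfile()
  writeLines(hash_src, tf)
  manifest <- list(
    config = cfg,
    files = setNames(as.list(unname(md5)), basename(files)),
    manifest_hash = unname(tools::md5sum(tf)),
    generated = format(Sys.time(), tz = "UTC")
  )
  unlink(tf)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("ceRNA pipeline bundle\n")
  for (cl in names(x$de)) {
    g <- glance(x$de[[cl]])
    cat(sprintf("  DE %-7s %4d features, %3d up, %3d down\n", cl, g$n,
                g$n_up, g$n_down))
  }
  for (cl in names(x$networks)) print(x$networks[[cl]])
  cat(sprintf("  hub mRNAs in both networks: %d\n", length(x$hub_mrnas)))
  invisible(x)
}
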