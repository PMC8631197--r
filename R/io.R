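#' Read and write the pipeline's tabular and sequence formats
#'
#' `read_count_matrix()` reads a wide counts TSV (columns `feature_id`,
#' `class`, `length`, then one column per sample) and validates it with
#' [as_count_table()], naming the offending row on negative or non-integer
#' values. `read_sample_sheet()` reads a two-column TSV (`sample_id`,
#' `group`). `read_fasta()`/`write_fasta()` go through Biostrings;
#' duplicate identifiers are an error and wrapped lines are concatenated.
#' `read_gmt()`/`write_gmt()` handle tab-separated gene-set collections
#' (name, description, members...); rows with fewer than three fields are
#' rejected.
#'
#' @param path File path.
#' @param require_integer Passed to [as_count_table()].
#' @return `read_count_matrix()`: a validated count tibble;
#'   `read_sample_sheet()`: a tibble; `read_fasta()`: a named character
#'   vector; `read_gmt()`: a tibble with columns `name`, `description` and
#'   list-column `genes`.
#' @export
read_count_matrix <- function(path, require_integer = TRUE) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("length" %in% names(x)) x$length <- as.numeric(x$length)
  as_count_table(x, require_integer = require_integer)
}

#' @rdname read_count_matrix
#' @param x Object to write (a count table, sequences, or a GMT tibble).
#' @export
write_count_matrix <- function(x, path) {
  readr::write_tsv(as_count_table(x, require_integer = FALSE), path)
  invisible(path)
}

#' @rdname read_count_matrix
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(x))) {
    abort("sample sheet must have columns sample_id and group")
  }
  as_tibble(x)
}

#' @rdname read_count_matrix
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA identifier: '", ids[duplicated(ids)][1], "'"))
  }
  setNames(as.character(set), ids)
}

#' @rdname read_count_matrix
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname read_count_matrix
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 fields"))
  }
  tibble(
    name = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = purrr::map(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_count_matrix
#' @export
write_gmt <- function(x, path) {
  lines <- purrr::pmap_chr(x, function(name, description, genes, ...) {
    paste(c(name, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a synthetic dataset to a fixture directory
#'
#' Emits one counts TSV per RNA class, the sample sheet, mapped-read
#' totals, miRNA and target FASTA files, truth tables (DE status, planted
#' triplets, recorded seed sites), a GMT built from the truth (planted
#' target mRNAs, split by direction), and the generator configuration —
#' everything [run_pipeline()] needs, in formats its readers round-trip
#' losslessly.
#'
#' @param dataset A `sponge_sim` from [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @return Tibble manifest: `file`, `bytes`, `md5`.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sponge_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)

  for (cl in names(dataset$counts)) {
    readr::write_tsv(dataset$counts[[cl]], fp(paste0("counts_", cl, ".tsv")))
  }
  readr::write_tsv(dataset$samples, fp("samples.tsv"))
  readr::write_tsv(
    tibble(sample_id = names(dataset$mapped_reads),
           mapped_reads = unname(dataset$mapped_reads)),
    fp("mapped_reads.tsv")
  )
  readr::write_tsv(dataset$truth_de, fp("truth_de.tsv"))
  trip <- dataset$truth_triplets
  readr::write_tsv(
    mutate(trip, mirna_ids = vapply(.data$mirna_ids, paste,
                                    character(1), collapse = ";")),
    fp("truth_triplets.tsv")
  )
  readr::write_tsv(dataset$truth_sites %||%
                     tibble(target_id = character(), mirna_id = character(),
                            start = integer(), end = integer(),
                            site_class = character()),
                   fp("truth_sites.tsv"))
  write_fasta(dataset$sequences$mirna, fp("sequences_mirna.fasta"))
  write_fasta(dataset$sequences$target, fp("sequences_target.fasta"))

  planted <- unique(trip$mrna_id)
  gmt <- tibble(
    name = "planted_mrna_targets",
    description = "mRNAs of planted ceRNA triplets",
    genes = list(planted)
  )
  for (d in c("up", "down")) {
    g <- unique(trip$mrna_id[trip$direction == d])
    if (length(g)) {
      gmt <- bind_rows(gmt, tibble(
        name = paste0("planted_mrna_", d),
        description = paste0("planted mRNAs, ", d, "regulated"),
        genes = list(g)
      ))
    }
  }
  write_gmt(gmt, fp("genesets.gmt"))
  yaml::write_yaml(unclass(dataset$config), fp("sim_config.yaml"))

  files <- c(paste0("counts_", names(dataset$counts), ".tsv"),
             "samples.tsv", "mapped_reads.tsv", "truth_de.tsv",
             "truth_triplets.tsv", "truth_sites.tsv",
             "sequences_mirna.fasta", "sequences_target.fasta",
             "genesets.gmt", "sim_config.yaml")
  tibble(
    file = files,
    bytes = file.size(file.path(dir, files)),
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
}

#' Read a fixture directory back into a dataset
#'
#' Inverse of [write_fixture()]: reconstructs counts, sample sheet, mapped
#' reads, truth tables, sequences and configuration from the fixture files.
#' Truth files are optional, so a directory holding only user data (counts,
#' samples, FASTA) also loads.
#'
#' @param dir Directory written by [write_fixture()] (or following its
#'   layout).
#' @return A `sponge_sim` list.
#' @export
read_fixture <- function(dir) {
  fp <- function(f) file.path(dir, f)
  classes <- c("mRNA", "lncRNA", "circRNA", "miRNA")
  counts <- purrr::map(setNames(classes, classes), function(cl) {
    read_count_matrix(fp(paste0("counts_", cl, ".tsv")))
  })
  samples <- read_sample_sheet(fp("samples.tsv"))
  mr <- readr::read_tsv(fp("mapped_reads.tsv"), show_col_types = FALSE,
                        progress = FALSE)
  mapped_reads <- setNames(mr$mapped_reads, mr$sample_id)

  opt_tsv <- function(f) {
    if (file.exists(fp(f))) {
      readr::read_tsv(fp(f), show_col_types = FALSE, progress = FALSE)
    } else NULL
  }
  truth_de <- opt_tsv("truth_de.tsv")
  trip <- opt_tsv("truth_triplets.tsv")
  if (!is.null(trip)) {
    ids <- as.character(trip$mirna_ids)
    ids[is.na(ids)] <- ""
    trip$mirna_ids <- purrr::map(strsplit(ids, ";", fixed = TRUE),
                                 as.character)
  }
  truth_sites <- opt_tsv("truth_sites.tsv")
  cfg <- if (file.exists(fp("sim_config.yaml"))) {
    raw <- yaml::read_yaml(fp("sim_config.yaml"))
    raw$n_features <- unlist(raw$n_features)
    raw$de_fraction <- unlist(raw$de_fraction)
    raw$nb_mean_range <- unlist(raw$nb_mean_range)
    structure(raw, class = "sim_config")
  } else NULL

  structure(list(
    counts = counts, samples = samples, mapped_reads = mapped_reads,
    truth_de = truth_de, truth_triplets = trip, truth_sites = truth_sites,
    sequences = list(
      mirna = if (file.exists(fp("sequences_mirna.fasta"))) {
        read_fasta(fp("sequences_mirna.fasta"))
      } else NULL,
      target = if (file.exists(fp("sequences_target.fasta"))) {
        read_fasta(fp("sequences_target.fasta"))
      } else NULL
    ),
    config = cfg
  ), class = "sponge_sim")
}
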