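#' Assemble a ceRNA network for one sponge class
#'
#' Runs the full sponge-inference pipeline for lncRNA- or circRNA-based
#' networks (the DMLCN/DMCCN construction): restrict every input to
#' differentially expressed features, keep miRNA-target binding pairs that
#' are strongly anti-correlated (`r < r_max`, `p < p_max`), keep sponge-mRNA
#' pairs that are strongly positively co-expressed (`r > r_min`,
#' `p < p_max`), require at least `min_shared_mirnas` miRNAs that survive
#' the anti-correlation filter against *both* partners, test each surviving
#' pair with the hypergeometric sponge test at `p_hyper_cut`, and emit a
#' typed node/edge graph containing the sponge, mRNA and shared miRNAs of
#' every accepted pair.
#'
#' The hypergeometric population N is the number of distinct DE miRNAs with
#' binding evidence on at least one DE feature of this contrast (before the
#' correlation filter); K and n are the filter-surviving miRNA counts of
#' the sponge and the mRNA and k their overlap.
#'
#' @param de_tables Named list of [call_de()] tables; must include `mRNA`,
#'   `miRNA` and the sponge class.
#' @param target_pairs Binding-evidence table from [build_target_table()]
#'   (`mirna_id`, `target_id`, ...).
#' @param expr Expression table or matrix covering all features of the
#'   contrast (samples in columns); correlations are computed across the
#'   pooled samples of both groups.
#' @param ce_class `"lncRNA"` or `"circRNA"`.
#' @param r_max,r_min,p_max Correlation cutoffs (defaults −0.9, 0.8, 0.05).
#' @param min_shared_mirnas Minimum shared miRNAs per sponge-mRNA pair
#'   (default 3).
#' @param p_hyper_cut Sponge-test cutoff (default 0.05).
#' @return A `cerna_network`: list with `nodes` (id, rna_type, direction),
#'   `edges` (id_a, id_b, edge_type, r, p, p_hyper), `pairs` (the accepted
#'   [CandidatePair][hypergeom_sponge_test()] table with N, K, n, k), and
#'   the thresholds used. Empty DE sets give an empty (valid) network.
#' @export
assemble_network <- function(de_tables, target_pairs, expr,
                             ce_class = c("lncRNA", "circRNA"),
                             r_max = -0.9, r_min = 0.8, p_max = 0.05,
                             min_shared_mirnas = 3, p_hyper_cut = 0.05) {
  ce_class <- match.arg(ce_class)
  for (cl in c("mRNA", "miRNA", ce_class)) {
    if (is.null(de_tables[[cl]])) {
      abort(paste0("de_tables must include a '", cl, "' table"))
    }
  }
  thresholds <- list(r_max = r_max, r_min = r_min, p_max = p_max,
                     min_shared_mirnas = min_shared_mirnas,
                     p_hyper_cut = p_hyper_cut)
  de_sub <- function(cl) {
    out <- dplyr::filter(as_tibble(de_tables[[cl]]), .data$direction != "ns")
    attr(out, "cutoffs") <- NULL
    class(out) <- class(tibble())
    out
  }
  de_m <- de_sub("mRNA")
  de_mi <- de_sub("miRNA")
  de_ce <- de_sub(ce_class)
  empty <- empty_network(ce_class, thresholds)
  if (nrow(de_m) == 0 || nrow(de_mi) == 0 || nrow(de_ce) == 0) return(empty)

  pairs <- as_tibble(target_pairs) |>
    dplyr::filter(.data$mirna_id %in% de_mi$feature_id,
                  .data$target_id %in% c(de_m$feature_id, de_ce$feature_id))
  if (nrow(pairs) == 0) return(empty)
  e <- expr_values(expr)
  retained <- filter_mirna_target(pairs, e, e, r_max = r_max, p_max = p_max)
  if (nrow(retained) == 0) return(empty)

  coex <- filter_coexpression(de_ce$feature_id, de_m$feature_id, e,
                              r_min = r_min, p_max = p_max)
  if (nrow(coex) == 0) return(empty)

  # Shared-miRNA evidence per coexpressed pair: k counts miRNAs surviving
  # the anti-correlation filter against BOTH partners, while K, n and N are
  # binding-evidence ("targeting") counts over the DE features — K and n do
  # not move with the correlation cutoffs, so tightening a threshold can
  # only shrink k and the test stays monotone (and non-degenerate when few
  # miRNAs survive filtering).
  mir_of <- split(retained$mirna_id, retained$target_id)
  bind_of <- split(pairs$mirna_id, pairs$target_id)
  N <- length(unique(pairs$mirna_id))
  cand <- coex |>
    mutate(
      shared_mirnas = purrr::map2(.data$ce_id, .data$mrna_id, function(a, b) {
        sort(intersect(mir_of[[a]] %||% character(0),
                       mir_of[[b]] %||% character(0)))
      }),
      k = lengths(.data$shared_mirnas),
      K = lengths(bind_of[.data$ce_id]),
      n = lengths(bind_of[.data$mrna_id]),
      N = N
    ) |>
    dplyr::filter(.data$k >= min_shared_mirnas)
  if (nrow(cand) == 0) return(empty)
  cand$p_hyper <- hypergeom_sponge_test(cand$N, cand$K, cand$n, cand$k)
  cand <- dplyr::filter(cand, .data$p_hyper < p_hyper_cut)
  if (nrow(cand) == 0) return(empty)

  # edges: one ce-mRNA edge per accepted pair, plus the miRNA spokes
  corr_lookup <- retained |>
    dplyr::select(id_a = "mirna_id", id_b = "target_id", "r", "p")
  spoke <- function(tid, type) {
    cand |>
      dplyr::select(sponge = "ce_id", mrna = "mrna_id",
                    shared = "shared_mirnas") |>
      mutate(other = if (tid == "ce") .data$sponge else .data$mrna) |>
      tidyr::unnest(cols = "shared") |>
      dplyr::transmute(id_a = .data$shared, id_b = .data$other,
                       edge_type = type) |>
      inner_join(corr_lookup, by = c("id_a", "id_b")) |>
      mutate(p_hyper = NA_real_)
  }
  edges <- bind_rows(
    cand |>
      dplyr::transmute(id_a = .data$ce_id, id_b = .data$mrna_id,
                       edge_type = "ce-mRNA", r = .data$r, p = .data$p,
                       p_hyper = .data$p_hyper),
    spoke("ce", "miRNA-ce"),
    spoke("mrna", "miRNA-mRNA")
  ) |>
    distinct(.data$id_a, .data$id_b, .data$edge_type, .keep_all = TRUE) |>
    arrange(.data$edge_type, .data$id_a, .data$id_b)

  dirs <- bind_rows(de_m, de_mi, de_ce) |>
    dplyr::select("feature_id", "class", "direction")
  node_ids <- unique(c(edges$id_a, edges$id_b))
  nodes <- dirs |>
    dplyr::filter(.data$feature_id %in% node_ids) |>
    dplyr::transmute(id = .data$feature_id, rna_type = .data$class,
                     direction = .data$direction) |>
    arrange(.data$rna_type, .data$id)

  structure(list(
    nodes = nodes, edges = edges,
    pairs = dplyr::select(cand, "ce_id", "mrna_id", "shared_mirnas",
                          "k", "K", "n", "N", "p_hyper", "r", "p"),
    ce_class = ce_class, thresholds = thresholds
  ), class = "cerna_network")
}

empty_network <- function(ce_class, thresholds) {
  structure(list(
    nodes = tibble(id = character(), rna_type = character(),
                   direction = character()),
    edges = tibble(id_a = character(), id_b = character(),
                   edge_type = character(), r = numeric(), p = numeric(),
                   p_hyper = numeric()),
    pairs = tibble(ce_id = character(), mrna_id = character(),
                   shared_mirnas = list(), k = integer(), K = integer(),
                   n = integer(), N = integer(), p_hyper = numeric(),
                   r = numeric(), p = numeric()),
    ce_class = ce_class, thresholds = thresholds
  ), class = "cerna_network")
}

#' Summarize a ceRNA network
#'
#' Node counts by RNA type and regulation direction, and edge counts by
#' edge type. Totals are consistent by construction: per-type up/down
#' counts sum to the type total, type totals sum to the node count, and
#' both the all-edge total and the ce-mRNA-only count are reported (network
#' size conventions differ on which to quote).
#'
#' @param net A `cerna_network`.
#' @return List with `nodes` (rna_type x direction counts), `edges`
#'   (per-type counts), `n_nodes`, `n_edges`, `n_ce_mrna_edges`.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  nodes <- net$nodes |>
    dplyr::count(.data$rna_type, .data$direction, name = "n")
  edges <- net$edges |> dplyr::count(.data$edge_type, name = "n")
  list(
    nodes = nodes, edges = edges,
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    n_ce_mrna_edges = sum(net$edges$edge_type == "ce-mRNA")
  )
}

#' @export
glance.cerna_network <- function(x, ...) {
  tibble(
    ce_class = x$ce_class,
    n_nodes = nrow(x$nodes),
    n_ce = sum(x$nodes$rna_type == x$ce_class),
    n_mirna = sum(x$nodes$rna_type == "miRNA"),
    n_mrna = sum(x$nodes$rna_type == "mRNA"),
    n_edges = nrow(x$edges),
    n_ce_mrna_edges = sum(x$edges$edge_type == "ce-mRNA")
  )
}

#' @export
tidy.cerna_network <- function(x, ...) x$edges

#' @export
print.cerna_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("ceRNA network (%s-based): %d nodes (%d %s, %d miRNA, %d mRNA), %d edges (%d ce-mRNA)\n",
              x$ce_class, g$n_nodes, g$n_ce, x$ce_class, g$n_mirna,
              g$n_mrna, g$n_edges, g$n_ce_mrna_edges))
  invisible(x)
}

#' Hub mRNAs shared by the lncRNA- and circRNA-based networks
#'
#' @param net_lnc,net_circ `cerna_network` objects from the same contrast.
#' @return Sorted character vector of mRNA node identifiers present in both.
#' @export
intersect_hub_mrnas <- function(net_lnc, net_circ) {
  m <- function(net) net$nodes$id[net$nodes$rna_type == "mRNA"]
  sort(intersect(m(net_lnc), m(net_circ)))
}

#' Export and import a ceRNA network
#'
#' Writes the network under `dir` as `<name>.nodes.tsv` and
#' `<name>.edges.tsv` (lossless round-trip through [read_network()]), a
#' Cytoscape SIF file (`source<TAB>edge_type<TAB>target`), and/or GraphML
#' with `rna_type`, `direction`, `edge_type`, `r`, `p`, `p_hyper`
#' attributes.
#'
#' @param net A `cerna_network`.
#' @param dir Output directory (created if missing).
#' @param name File stem.
#' @param formats Subset of `c("tsv", "sif", "graphml")`.
#' @return Character vector of the files written.
#' @export
export_network <- function(net, dir, name = "cerna",
                           formats = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "cerna_network"))
  bad <- setdiff(formats, c("tsv", "sif", "graphml"))
  if (length(bad)) abort(paste0("unknown format: ", bad[1]))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  if ("tsv" %in% formats) {
    nf <- file.path(dir, paste0(name, ".nodes.tsv"))
    ef <- file.path(dir, paste0(name, ".edges.tsv"))
    readr::write_tsv(net$nodes, nf)
    readr::write_tsv(net$edges, ef)
    out <- c(out, nf, ef)
  }
  if ("sif" %in% formats) {
    sf <- file.path(dir, paste0(name, ".sif"))
    readr::write_lines(
      sprintf("%s\t%s\t%s", net$edges$id_a, net$edges$edge_type,
              net$edges$id_b),
      sf
    )
    out <- c(out, sf)
  }
  if ("graphml" %in% formats) {
    gf <- file.path(dir, paste0(name, ".graphml"))
    g <- as_igraph(net)
    igraph::write_graph(g, gf, format = "graphml")
    out <- c(out, gf)
  }
  invisible(out)
}

#' @rdname export_network
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' @rdname export_network
#' @param ce_class Sponge class recorded on import; inferred from the node
#'   types when `NULL`.
#' @export
read_network <- function(dir, name = "cerna", ce_class = NULL) {
  nodes <- readr::read_tsv(file.path(dir, paste0(name, ".nodes.tsv")),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             id = readr::col_character(),
                             rna_type = readr::col_character(),
                             direction = readr::col_character()
                           ))
  edges <- readr::read_tsv(file.path(dir, paste0(name, ".edges.tsv")),
                           show_col_types = FALSE, progress = FALSE)
  if (is.null(ce_class)) {
    ce_class <- if ("circRNA" %in% nodes$rna_type) "circRNA" else "lncRNA"
  }
  structure(list(
    nodes = as_tibble(nodes), edges = as_tibble(edges), pairs = NULL,
    ce_class = ce_class, thresholds = NULL
  ), class = "cerna_network")
}
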