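#' Build the causal graph of a single induction experiment
#'
#' Direct edges connect each attributed driver (psi above the driver
#' cutoff, `driver_flag`) to its target, weighted by psi. Indirect edges
#' connect the induced gene to every differentially expressed gene
#' (one that survived hard-thresholding in this experiment), regardless of
#' whether a direct explanation exists. The strongest driver of each
#' (target, kind) response is annotated.
#'
#' @param attributions attribution table for one experiment (rows of
#'   `attribute_all()$attributions` with this experiment).
#' @param de_genes character vector of differentially expressed genes in
#'   the experiment.
#' @param induced_gene the induced regulator.
#' @param experiment experiment identifier.
#' @return object of class `causal_graph`: list with `nodes` (data.frame
#'   gene, induced, regulator) and `edges` (data.frame source, target,
#'   type, weight, experiment, strongest).
#' @export
build_experiment_graph <- function(attributions, de_genes, induced_gene,
                                   experiment) {
  direct <- if (nrow(attributions)) {
    attributions[attributions$driver_flag &
                   attributions$experiment == experiment, , drop = FALSE]
  } else attributions
  edges <- data.frame(source = character(0), target = character(0),
                      type = character(0), weight = numeric(0),
                      experiment = character(0), strongest = logical(0))
  if (NROW(direct)) {
    strongest <- unlist(lapply(
      split(seq_len(nrow(direct)),
            paste(direct$target, direct$kind, sep = "\r")),
      function(ii) ii[which.max(direct$psi[ii])]))
    edges <- rbind(edges, data.frame(
      source = direct$regulator, target = direct$target, type = "direct",
      weight = direct$psi, experiment = experiment,
      strongest = seq_len(nrow(direct)) %in% strongest,
      stringsAsFactors = FALSE))
  }
  ind_targets <- setdiff(de_genes, induced_gene)
  if (length(ind_targets)) {
    edges <- rbind(edges, data.frame(
      source = induced_gene, target = ind_targets, type = "indirect",
      weight = NA_real_, experiment = experiment, strongest = FALSE,
      stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  genes <- unique(c(induced_gene, edges$source, edges$target))
  nodes <- data.frame(gene = genes, induced = genes == induced_gene,
                      regulator = genes %in% edges$source[
                        edges$type == "direct"],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' Synthesize experiment-level graphs into a meta-graph
#'
#' Takes the union of edges across experiment graphs, recording per-edge
#' support (number of distinct experiments contributing the edge) and a
#' per-node hub score (number of distinct direct targets across all
#' experiments).
#'
#' @param graphs list of `causal_graph` objects.
#' @return `causal_graph` whose `edges` gain a `support` column (the
#'   `experiment` column lists the contributing experiments,
#'   comma-separated) and whose `nodes` gain `hub_score`.
#' @export
synthesize_meta_graph <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  all_edges <- do.call(rbind, lapply(graphs, function(g) g$edges))
  key <- paste(all_edges$source, all_edges$target, all_edges$type,
               sep = "\r")
  agg <- lapply(split(seq_len(nrow(all_edges)), key), function(ii) {
    e <- all_edges[ii[1], c("source", "target", "type")]
    e$weight <- mean(all_edges$weight[ii])
    e$experiment <- paste(unique(all_edges$experiment[ii]), collapse = ",")
    e$support <- length(unique(all_edges$experiment[ii]))
    e
  })
  edges <- do.call(rbind, agg)
  rownames(edges) <- NULL
  direct <- edges[edges$type == "direct", , drop = FALSE]
  hub <- vapply(unique(c(edges$source, edges$target)), function(g) {
    length(unique(direct$target[direct$source == g]))
  }, integer(1))
  nodes <- data.frame(gene = names(hub),
                      induced = names(hub) %in% unlist(
                        lapply(graphs, function(g)
                          g$nodes$gene[g$nodes$induced])),
                      regulator = names(hub) %in% direct$source,
                      hub_score = unname(hub), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("causal_graph: %d nodes, %d edges (%d direct, %d indirect)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "direct"),
              sum(x$edges$type == "indirect")))
  invisible(x)
}

# mid-rank (tie-averaged) AUC: P(score_pos > score_neg) + 0.5 P(equal)
rank_auc <- function(score, label) {
  n_pos <- sum(label)
  n_neg <- sum(!label)
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate scored edges against a reference network with ROC and a
#' degree-preserving permutation null
#'
#' Scored directed edges are labeled positive when the (undirected) pair is
#' present in the reference network; all other scored pairs are negatives.
#' The AUC is computed by mid-rank (tie-averaged) trapezoid. The null
#' permutes the pairing of sources and targets (preserving the counts of
#' each cause and each effect while randomizing which cause points at which
#' effect) `n_perm` times and recomputes the AUC.
#'
#' @param edge_scores data.frame with columns source, target, score.
#' @param reference_edges data.frame/matrix with two columns of gene
#'   identifiers.
#' @param n_perm number of permutations (default 25).
#' @param seed RNG seed for the permutations.
#' @param directed treat the reference as directed (first column regulator,
#'   second column target). Default FALSE: published interaction networks
#'   are undirected, so a scored directed edge matches in either
#'   orientation. Use TRUE when evaluating against a ground truth whose
#'   direction is known, such as a simulated network.
#' @return object of class `roc_result`: list with `edges` (scored, labeled,
#'   in descending score order), `auc`, and `perm_aucs`.
#' @export
evaluate_roc <- function(edge_scores, reference_edges, n_perm = 25,
                         seed = NULL, directed = FALSE) {
  ref <- paste(reference_edges[[1]], reference_edges[[2]], sep = "\r")
  if (!directed) {
    ref <- c(ref, paste(reference_edges[[2]], reference_edges[[1]],
                        sep = "\r"))
  }
  ref <- unique(ref)
  lab <- paste(edge_scores$source, edge_scores$target, sep = "\r") %in% ref
  if (!any(lab)) stop("no scored edge overlaps the reference: AUC undefined")
  if (all(lab)) stop("every scored edge is in the reference: AUC undefined")
  auc <- rank_auc(edge_scores$score, lab)
  perm_aucs <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    tgt <- sample(edge_scores$target)
    lab_p <- paste(edge_scores$source, tgt, sep = "\r") %in% ref
    if (!any(lab_p) || all(lab_p)) return(NA_real_)
    rank_auc(edge_scores$score, lab_p)
  }, numeric(1)))
  ord <- order(-edge_scores$score, edge_scores$source, edge_scores$target)
  structure(list(
    edges = cbind(edge_scores[ord, ], positive = lab[ord]),
    auc = auc, perm_aucs = perm_aucs), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (%d edges, %d positives); perm null %.3f\n",
              x$auc, nrow(x$edges), sum(x$edges$positive),
              mean(x$perm_aucs, na.rm = TRUE)))
  invisible(x)
}

#' Score induced-gene edges by observed rise time
#'
#' The comparator edge ranking that uses only observed kinetics: each
#' responder in an experiment yields a candidate edge from the induced gene,
#' scored by negative rise time (earlier responses rank higher). Ties are
#' broken by gene identifier (stable, documented order).
#'
#' @param fits kinetic fits table from [fit_kinetics()].
#' @param induced_map named character vector experiment -> induced gene.
#' @return data.frame (source, target, score) sorted by descending score
#'   with the identifier tie-break applied.
#' @export
rank_by_rise_time <- function(fits, induced_map) {
  df <- data.frame(source = unname(induced_map[fits$experiment]),
                   target = fits$gene, score = -fits$t_rise,
                   stringsAsFactors = FALSE)
  df <- df[df$source != df$target, ]
  df[order(-df$score, df$target), ]
}

#' Gene-set overlap enrichment of predicted targets
#'
#' Hypergeometric upper-tail test of the overlap between a regulator's
#' predicted target set and each gene set, Benjamini-Hochberg corrected
#' across sets. Used to link predicted regulators to functional categories.
#'
#' @param target_set character vector of predicted targets.
#' @param gene_sets named list of gene identifier vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of measured genes.
#' @param q_cutoff FDR threshold for reporting a link (default 0.05).
#' @return data.frame (set, set_size, overlap, p, padj, linked), one row per
#'   non-empty set; empty sets are skipped with a warning.
#' @export
enrich_overlap <- function(target_set, gene_sets, universe,
                           q_cutoff = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  target_set <- intersect(target_set, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], universe)
    if (length(gs) == 0) {
      warning("gene set ", nm, " has no genes in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(target_set, gs))
    p <- stats::phyper(k - 1, length(gs), length(universe) - length(gs),
                       length(target_set), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(gs), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$linked <- out$padj < q_cutoff
  out
}
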