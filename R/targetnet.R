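#' Build a protein-ligand interaction network
#'
#' Constructs the bipartite network used for ligand-based reverse target
#' prediction: proteins are nodes, ligands (with their six precomputed
#' fingerprints) are attached by interaction edges.  Ligands are deduplicated
#' by canonical SMILES; rows whose SMILES do not parse are skipped and
#' counted.
#'
#' @param table Data frame with columns `protein_id`, `ligand_id`, `smiles`.
#' @param nbits Hashed fingerprint length (default 2048).
#' @return An `interaction_network`: list with `proteins` (character),
#'   `ligands` (tibble `ligand_id`, `smiles_canonical`, `fps` list-column),
#'   `edges` (tibble `protein_id`, `ligand_id`), `n_skipped`, `nbits`.
#' @export
build_network <- function(table, nbits = 2048L) {
  need <- c("protein_id", "ligand_id", "smiles")
  if (!all(need %in% names(table))) {
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0) stop("interaction table is empty")
  p <- parse_smiles(as.character(table$smiles))
  n_skipped <- sum(!p$valid)
  if (n_skipped > 0) {
    message("build_network: skipped ", n_skipped, " row(s) with invalid SMILES")
  }
  keep <- p$valid
  if (!any(keep)) stop("no valid rows: the network would be empty", call. = FALSE)
  tab <- tibble::tibble(protein_id = as.character(table$protein_id)[keep],
                        ligand_id = as.character(table$ligand_id)[keep],
                        canonical = p$canonical[keep])
  # dedupe ligands on canonical structure; the first ligand_id seen wins
  first <- !duplicated(tab$canonical)
  lig_id <- tab$ligand_id[first]
  lig_smi <- tab$canonical[first]
  id_of <- stats::setNames(lig_id, lig_smi)
  fps <- fingerprints(lig_smi, nbits = nbits)
  ligands <- tibble::tibble(ligand_id = lig_id, smiles_canonical = lig_smi,
                            fps = fps)
  edges <- unique(tibble::tibble(protein_id = tab$protein_id,
                                 ligand_id = unname(id_of[tab$canonical])))
  net <- list(proteins = sort(unique(edges$protein_id)), ligands = ligands,
              edges = edges, n_skipped = n_skipped, nbits = as.integer(nbits))
  class(net) <- "interaction_network"
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network: ", length(x$proteins), " proteins, ",
      nrow(x$ligands), " ligands, ", nrow(x$edges), " edges",
      if (x$n_skipped > 0) paste0(" (", x$n_skipped, " rows skipped)"), ">\n",
      sep = "")
  invisible(x)
}

#' Score a query compound against every network ligand
#'
#' For each ligand and each of the six fingerprint kinds, the per-fingerprint
#' similarity value is the sum of the six similarity measures; the `total` is
#' the sum over fingerprints (36 pairwise values per ligand in all).
#'
#' @param query A SMILES string.
#' @param net An [build_network()] result.
#' @return Tibble with `ligand_id`, one column per fingerprint kind, `total`,
#'   sorted as the network ligands are stored.
#' @export
score_query <- function(query, net) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$ligands) == 0) stop("empty network")
  qfps <- fingerprints(query, nbits = net$nbits)[[1]]
  per_kind <- vapply(net$ligands$fps, function(lf) {
    vapply(FP_KINDS,
           function(k) sum(similarity_all(qfps[[k]], lf[[k]], strict = FALSE)),
           numeric(1))
  }, numeric(length(FP_KINDS)))
  per_kind <- t(per_kind)  # ligands x kinds
  out <- tibble::as_tibble(as.data.frame(per_kind))
  names(out) <- FP_KINDS
  out <- tibble::tibble(ligand_id = net$ligands$ligand_id, out,
                        total = rowSums(per_kind))
  out
}

#' Select the most similar network drugs
#'
#' Top-`k` ligands by total similarity score; ties at the cut are broken by
#' lexicographic ligand id so selection is deterministic.
#'
#' @param scores Result of [score_query()].
#' @param top_k Number of drugs to keep (default 100).
#' @return The selected rows of `scores`, ordered by decreasing total.
#' @export
select_drugs <- function(scores, top_k = 100L) {
  stopifnot(top_k >= 1)
  if (top_k > nrow(scores)) {
    warning("top_k (", top_k, ") exceeds number of ligands (", nrow(scores),
            "); returning all")
    top_k <- nrow(scores)
  }
  ord <- order(-scores$total, scores$ligand_id)
  scores[ord, ][seq_len(top_k), ]
}

#' Rank proteins by propagated similarity scores
#'
#' Propagates each selected drug's per-fingerprint similarity score to every
#' protein it interacts with, then per fingerprint sorts proteins by score,
#' assigns integer rank values (N for the best down to 1 for the worst, ties
#' broken by lexicographic protein id) and normalises them to rank scores
#' `rank_value / sum(rank_values)`.  A protein's total `R` is the sum of its
#' rank scores over the six fingerprints, and the modified total rank score
#' is `R_tilde = R / max(R)`, so the top-ranked target attains exactly 1.
#'
#' @param net An `interaction_network`.
#' @param selected Result of [select_drugs()] (or [score_query()] to use all
#'   ligands).
#' @return A `protein_rank_table`: list with `table` (tibble `protein_id`,
#'   `R`, `R_tilde`, `rank`, sorted by `R_tilde` descending) and `per_kind`
#'   (long tibble `kind`, `protein_id`, `score`, `rank_value`, `rank_score`).
#' @export
rank_proteins <- function(net, selected) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(selected) == 0) stop("no selected drugs")
  edges <- net$edges[net$edges$ligand_id %in% selected$ligand_id, ]
  if (nrow(edges) == 0) stop("no protein is connected to any selected drug")
  proteins <- sort(unique(edges$protein_id))
  n <- length(proteins)
  per_kind <- lapply(FP_KINDS, function(k) {
    drug_score <- stats::setNames(selected[[k]], selected$ligand_id)
    score <- unname(vapply(proteins, function(p) {
      sum(drug_score[edges$ligand_id[edges$protein_id == p]])
    }, numeric(1)))
    ord <- order(-score, proteins)
    rank_value <- integer(n)
    rank_value[ord] <- n:1
    rank_score <- rank_value / sum(rank_value)
    tibble::tibble(kind = k, protein_id = proteins, score = score,
                   rank_value = rank_value, rank_score = rank_score)
  })
  per_kind <- do.call(rbind, per_kind)
  R <- unname(vapply(proteins, function(p) {
    sum(per_kind$rank_score[per_kind$protein_id == p])
  }, numeric(1)))
  table <- tibble::tibble(protein_id = proteins, R = R, R_tilde = R / max(R))
  ord <- order(-table$R_tilde, table$protein_id)
  table <- table[ord, ]
  table$rank <- seq_len(n)
  out <- list(table = table, per_kind = per_kind)
  class(out) <- "protein_rank_table"
  out
}

#' @export
print.protein_rank_table <- function(x, ...) {
  cat("<protein_rank_table: ", nrow(x$table), " proteins>\n", sep = "")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Reverse target prediction in one call
#'
#' Runs [score_query()], [select_drugs()] and [rank_proteins()].
#'
#' @inheritParams score_query
#' @inheritParams select_drugs
#' @return A `protein_rank_table`.
#' @export
predict_targets <- function(query, net, top_k = 100L) {
  rank_proteins(net, select_drugs(score_query(query, net), top_k = top_k))
}

#' Write a protein rank table to CSV
#' @param ranks A `protein_rank_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(ranks, path) {
  utils::write.csv(as.data.frame(ranks$table), path, row.names = FALSE)
  invisible(path)
}
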