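toy_table <- function() {
  tibble::tibble(
    protein_id = c("PA", "PA", "PB"),
    ligand_id = c("L1", "L2", "L2b"),
    smiles = c("CCO", "c1ccccc1O", "Oc1ccccc1"))  # L2b duplicates L2
}

test_that("network construction deduplicates ligands and counts skipped rows", {
  net <- build_network(toy_table())
  expect_identical(net$proteins, c("PA", "PB"))
  expect_identical(nrow(net$ligands), 2L)
  expect_identical(nrow(net$edges), 3L)

  dup <- toy_table()[c(1, 1, 2, 3), ]
  expect_identical(nrow(build_network(dup)$edges), 3L)

  bad <- toy_table()
  bad$smiles[1] <- "C1CC"
  expect_message(net2 <- build_network(bad), "skipped 1")
  expect_identical(net2$n_skipped, 1L)
  expect_error(suppressMessages(
    build_network(tibble::tibble(protein_id = "P", ligand_id = "L",
                                 smiles = "C1CC"))), "empty")
  expect_error(build_network(data.frame(protein_id = character(0),
                                        ligand_id = character(0),
                                        smiles = character(0))), "empty")
})

test_that("a query identical to a network ligand scores 6 per fingerprint, 36 total", {
  net <- build_network(toy_table())
  sc <- score_query("c1ccccc1O", net)
  row <- sc[sc$ligand_id == "L2", ]
  for (k in FP_KINDS) expect_equal(row[[k]], 6)
  expect_equal(row$total, 36)
  # totals are the sum of the per-fingerprint components
  expect_equal(sc$total, rowSums(as.matrix(sc[, FP_KINDS])))
})

test_that("query scores are invariant to ligand row order", {
  net1 <- build_network(toy_table())
  net2 <- build_network(toy_table()[c(3, 1, 2), ])
  s1 <- score_query("CCNC(=O)c1ccccc1", net1)
  s2 <- score_query("CCNC(=O)c1ccccc1", net2)
  s1 <- s1[order(s1$ligand_id), ]
  s2 <- s2[order(s2$ligand_id), ]
  expect_equal(s1$total, s2$total)
})

test_that("drug selection keeps the top-k by total with lexicographic tie-break", {
  sc <- tibble::tibble(ligand_id = c("b", "a", "c"), total = c(9, 7, 5))
  expect_identical(select_drugs(sc, 2)$ligand_id, c("b", "a"))
  tie <- tibble::tibble(ligand_id = c("z", "a"), total = c(5, 5))
  expect_identical(select_drugs(tie, 1)$ligand_id, "a")
  expect_identical(select_drugs(sc, 3)$ligand_id, c("b", "a", "c"))
  expect_warning(all3 <- select_drugs(sc, 10), "exceeds")
  expect_identical(nrow(all3), 3L)
  expect_error(select_drugs(sc, 0))
})

fake_net <- function(edges) {
  structure(list(proteins = sort(unique(edges$protein_id)),
                 ligands = tibble::tibble(), edges = edges, n_skipped = 0L,
                 nbits = 2048L), class = "interaction_network")
}

fake_selected <- function(ids, per_kind_score) {
  sc <- tibble::tibble(ligand_id = ids)
  for (k in FP_KINDS) sc[[k]] <- per_kind_score
  sc$total <- rowSums(as.matrix(sc[, FP_KINDS]))
  sc
}

test_that("rank scores realise rank_value / sum(rank_values) and R_tilde = R/Rmax", {
  # three proteins, one exclusive ligand each, scores 3 > 2 > 1 in all kinds
  edges <- tibble::tibble(protein_id = c("PA", "PB", "PC"),
                          ligand_id = c("l1", "l2", "l3"))
  sel <- fake_selected(c("l1", "l2", "l3"), c(3, 2, 1))
  rt <- rank_proteins(fake_net(edges), sel)
  one <- rt$per_kind[rt$per_kind$kind == "PATH", ]
  expect_equal(one$rank_score[match(c("PA", "PB", "PC"), one$protein_id)],
               c(3, 2, 1) / 6, tolerance = 1e-12)
  expect_equal(rt$table$R_tilde[match(c("PA", "PB", "PC"), rt$table$protein_id)],
               c(1, 2 / 3, 1 / 3), tolerance = 1e-12)
  # per fingerprint the rank scores are a partition of unity
  for (k in FP_KINDS) {
    expect_equal(sum(rt$per_kind$rank_score[rt$per_kind$kind == k]), 1,
                 tolerance = 1e-12)
  }
  expect_equal(max(rt$table$R_tilde), 1)
})

test_that("rank ties get distinct consecutive values by lexicographic protein id", {
  edges <- tibble::tibble(protein_id = c("PZ", "PA"), ligand_id = c("l1", "l2"))
  sel <- fake_selected(c("l1", "l2"), c(1, 1))
  rt <- rank_proteins(fake_net(edges), sel)
  one <- rt$per_kind[rt$per_kind$kind == "PATH", ]
  expect_identical(sort(one$rank_value), 1:2)
  expect_identical(one$protein_id[one$rank_value == 2], "PA")
})

test_that("rank_proteins demands a connected selection", {
  edges <- tibble::tibble(protein_id = "PA", ligand_id = "l1")
  sel <- fake_selected("lX", 1)
  expect_error(rank_proteins(fake_net(edges), sel), "connected")
})

test_that("the planted target of a synthetic network attains R_tilde = 1", {
  for (seed in c(21, 22)) {
    fix <- generate_network(n_proteins = 8, ligands_per_protein = 4, seed = seed)
    net <- build_network(fix$table)
    rt <- predict_targets(fix$query, net, top_k = 10)
    expect_identical(rt$table$protein_id[1], fix$planted)
    expect_equal(rt$table$R_tilde[1], 1)
  }
})

test_that("rank tables serialise to CSV", {
  fix <- generate_network(n_proteins = 4, ligands_per_protein = 3, seed = 30)
  rt <- predict_targets(fix$query, build_network(fix$table), top_k = 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_rank_table(rt, tmp)
  df <- read.csv(tmp)
  expect_identical(names(df), c("protein_id", "R", "R_tilde", "rank"))
  expect_equal(df$R_tilde[1], 1)
})
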