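test_that("canonical small molecules parse to the expected graph shapes", {
  methane <- smiles_to_graph("C")
  expect_equal(methane$n_atoms, 1)
  expect_equal(sum(methane$adjacency) / 2, 0)

  ethane <- smiles_to_graph("CC")
  expect_equal(ethane$n_atoms, 2)
  expect_equal(sum(ethane$adjacency) / 2, 1)

  benzene <- smiles_to_graph("c1ccccc1")
  expect_equal(benzene$n_atoms, 6)
  expect_equal(sum(benzene$adjacency) / 2, 6)
  expect_true(all(benzene$aromatic))
  expect_true(all(benzene$atom_features[, "aromatic"] == 1))

  # branches, ring closures, two-character elements, brackets
  aspirin <- smiles_to_graph("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(aspirin$n_atoms, 13)
  expect_equal(sum(aspirin$adjacency) / 2, 13)
  expect_equal(smiles_to_graph("ClCCl")$atom_symbols, c("Cl", "C", "Cl"))
  expect_equal(sum(smiles_to_graph("c1cc[nH]c1")$aromatic), 5)
})

test_that("malformed SMILES are rejected with the offending string", {
  expect_error(smiles_to_graph("C(("), "unbalanced")
  expect_error(smiles_to_graph("C1CC"), "unclosed ring")
  expect_error(smiles_to_graph("C.C"), "multi-component")
  expect_error(smiles_to_graph("C$"), "unrecognised")
  expect_error(smiles_to_graph(""), "empty")
})

test_that("every packaged toy SMILES parses and featurizes", {
  for (s in toy_smiles()) {
    g <- smiles_to_graph(s)
    expect_gte(g$n_atoms, 1)
    expect_true(all(rowSums(g$atom_features[, 1:21, drop = FALSE]) == 1))
    expect_equal(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
  }
})

test_that("atom and bond counts agree with an independent chemistry parser", {
  skip_if_not_installed("ChemmineR")
  smiles <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "C1CCNCC1",
              "N#Cc1ccccc1", "OC(=O)CC(=O)O")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  for (k in seq_along(smiles)) {
    g <- smiles_to_graph(smiles[k])
    expect_equal(g$n_atoms, nrow(ChemmineR::atomblock(sdf[[k]])),
                 info = smiles[k])
    expect_equal(sum(g$adjacency) / 2, nrow(ChemmineR::bondblock(sdf[[k]])),
                 info = smiles[k])
  }
})

test_that("zero weights and single atoms reduce the encoder to closed form", {
  params <- gcn_params(n_layers = 2, d_out = 4, seed = 40)
  zero <- params
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  expect_true(all(gcn_encode(smiles_to_graph("CCO"), zero) == 0))

  # single heavy atom: chained dense transforms of its one-hot feature row
  g <- smiles_to_graph("C")
  s <- gcn_encode(g, params)
  h <- g$atom_features
  for (w in params$weights) h <- pmax(h %*% w, 0)
  expect_lt(max(abs(s - as.numeric(h))), 1e-12)
})

test_that("embeddings are invariant to atom relabelling", {
  set.seed(41)
  params <- gcn_params(n_layers = 3, d_out = 8, seed = 42)
  smiles_pool <- toy_smiles()[vapply(toy_smiles(),
                                     function(s) smiles_to_graph(s)$n_atoms > 2,
                                     logical(1))]
  for (s in sample(smiles_pool, 20)) {
    g <- smiles_to_graph(s)
    base <- gcn_encode(g, params)
    for (rep in 1:5) {
      perm <- sample.int(g$n_atoms)
      gp <- g
      gp$adjacency <- g$adjacency[perm, perm]
      gp$atom_symbols <- g$atom_symbols[perm]
      gp$aromatic <- g$aromatic[perm]
      gp$atom_features <- g$atom_features[perm, , drop = FALSE]
      expect_lt(max(abs(gcn_encode(gp, params) - base)), 1e-6)
    }
  }
})

test_that("pooled coordinates stay inside the atom-wise activation envelope", {
  params <- gcn_params(n_layers = 2, d_out = 5, seed = 43)
  g <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1")
  pre <- synergraph:::mol_precompute(g)
  h <- pre$feats
  for (w in params$weights) h <- pmax(pre$prop %*% h %*% w, 0)
  pooled <- gcn_encode(g, params)
  expect_true(all(pooled >= apply(h, 2, min) - 1e-12))
  expect_true(all(pooled <= apply(h, 2, max) + 1e-12))
})

test_that("encoder gradients match central finite differences on ethane", {
  g <- smiles_to_graph("CC")
  pre <- synergraph:::mol_precompute(g)
  p0 <- gcn_params(n_layers = 2, d_out = 3, seed = 44)
  flat <- stats::setNames(p0$weights, c("W1", "W2"))
  loss_fn <- function(fp) {
    synergraph:::ad_tape_begin()
    nodes <- lapply(fp, synergraph:::ad_param)
    out <- synergraph:::gcn_forward(pre, nodes)
    loss <- synergraph:::ad_mse(out, matrix(0.2, 1, 3))
    synergraph:::ad_backward(loss)
    synergraph:::ad_tape_end()
    list(value = loss$value, grads = lapply(nodes, function(n) n$grad))
  }
  expect_lt(gradcheck(loss_fn, flat), 1e-4)
})

test_that("fallback fingerprints are deterministic and structure-sensitive", {
  a <- fallback_fingerprint("CCO")
  b <- fallback_fingerprint("CCO")
  expect_identical(a, b)
  expect_equal(length(a), 300)
  expect_gt(max(abs(fallback_fingerprint("C") -
                      fallback_fingerprint("c1ccccc1"))), 1e-6)
  mols <- toy_smiles()[1:10]
  mat <- t(vapply(mols, fallback_fingerprint, numeric(300)))
  expect_true(all(sqrt(rowSums(mat^2)) > 0))
  expect_lte(qr(mat)$rank, 10)
  # identical SMILES rows are identical; distinct molecules differ
  expect_gt(min(stats::dist(mat)), 0)
})
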