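test_that("Murcko scaffolds strip side chains and keep ring-linker unions", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), canonical_smiles("c1ccccc1"))
  expect_equal(murcko_scaffold("Oc1ccc(-c2ccccc2)cc1"),
               canonical_smiles("c1ccc(-c2ccccc2)cc1"))
  expect_equal(murcko_scaffold("CCCCCC"), "")
  # acetophenone: exocyclic carbonyl is part of the side chain
  expect_equal(murcko_scaffold("CC(=O)c1ccccc1"),
               canonical_smiles("c1ccccc1"))
  # but a carbonyl on a ring atom or linker is retained
  expect_equal(murcko_scaffold("O=C1CCCCC1CCC"),
               canonical_smiles("O=C1CCCCC1"))
  expect_equal(murcko_scaffold("c1ccccc1C(=O)c1ccccc1C"),
               canonical_smiles("O=C(c1ccccc1)c1ccccc1"))
})

test_that("cyclic skeletons genericize heteroatoms and bond orders", {
  benz <- cyclic_skeleton("c1ccccc1")
  expect_equal(cyclic_skeleton("c1ccncc1"), benz)
  expect_equal(cyclic_skeleton("C1=CCCCC1"), benz)
  expect_equal(cyclic_skeleton("c1ccc2ccccc2c1"),
               cyclic_skeleton("C1CCC2CCCCC2C1"))
})

test_that("skeleton of a scaffold equals skeleton of the molecule", {
  smis <- fixture_clean()$records$smiles[seq(1, 276, by = 10)]
  sc <- murcko_scaffold(smis)
  expect_identical(cyclic_skeleton(sc), cyclic_skeleton(smis))
  # and scaffolding is idempotent
  expect_identical(murcko_scaffold(sc), sc)
})

test_that("scaffold table frequencies, EF identities and conservation hold", {
  fx <- fixture_clean()
  st <- scaffold_table(fx$records, scaffolds = fixture_scaffolds(),
                       skeletons = fixture_skeletons())
  n <- nrow(fx$records)
  expect_equal(sum(st$frequency), n)
  expect_true(all(diff(st$frequency) <= 0))
  p <- attr(st, "active_proportion")
  expect_equal(sum(st$n_active) / n, p)
  # EF identities: 1/p iff all members active, 0 iff none
  all_active <- st$n_active == st$frequency
  expect_equal(abs(st$ef_exact - 1 / p) < 1e-12, all_active)
  expect_equal(st$ef_exact == 0, st$n_active == 0)
  # conservation: frequency-weighted scaffold active proportions = dataset
  expect_equal(sum(st$frequency * (st$n_active / st$frequency)) / n, p)
})

test_that("EF arithmetic reproduces the worked rounded-proportion example", {
  # 683 compounds of which 351 active; proportion rounds to 0.51; a fully
  # active scaffold then has EF = 1/0.51 = 1.961
  n <- 683; n_act <- 351
  sc <- c(rep("S1", 10), paste0("X", seq_len(n - 10)))
  act <- c(rep(TRUE, 10), rep(TRUE, n_act - 10), rep(FALSE, n - n_act))
  recs <- data.frame(compound_id = sprintf("c%03d", seq_len(n)),
                     smiles = "c1ccccc1",
                     pic50 = ifelse(act, 7.5, 6.5))
  st <- scaffold_table(recs, scaffolds = sc, skeletons = sc)
  expect_equal(attr(st, "active_proportion_rounded"), 0.51)
  s1 <- st[st$scaffold_smiles == "S1", ]
  expect_equal(round(s1$ef, 3), 1.961)
  expect_equal(s1$ef_exact, 1 / (351 / 683))
})

test_that("diversity ratios and report match direct counting", {
  expect_equal(as.numeric(diversity_ratios(683, 268, 162, 150)),
               c(0.392, 0.237, 0.220, 0.560))
  fx <- fixture_clean()
  dv <- diversity_report(fx$records, scaffolds = fixture_scaffolds(),
                         skeletons = fixture_skeletons())
  expect_equal(dv$N, nrow(fx$records))
  expect_equal(dv$Ns, length(unique(fixture_scaffolds())))
  expect_equal(dv$Nss, sum(table(fixture_scaffolds()) == 1))
  expect_lte(dv$Ncsk, dv$Ns)
  expect_true(all(c(dv$Ns_N, dv$Nss_N, dv$Ncsk_N, dv$Ncsk_Ns) >= 0 &
                  c(dv$Ns_N, dv$Nss_N, dv$Ncsk_N, dv$Ncsk_Ns) <= 1))
  # subset filtering
  act <- fx$records$pic50 >= 7
  dva <- diversity_report(fx$records, subset = act,
                          scaffolds = fixture_scaffolds(),
                          skeletons = fixture_skeletons())
  expect_equal(dva$N, sum(act))
  expect_error(diversity_report(fx$records, subset = rep(FALSE, 276),
                                scaffolds = fixture_scaffolds(),
                                skeletons = fixture_skeletons()), "empty")
})

test_that("representative scaffolds satisfy frequency OR enrichment", {
  st <- data.frame(scaffold_smiles = c("A", "B", "C", "D"),
                   skeleton_smiles = c("A", "B", "C", "D"),
                   frequency = c(12, 2, 3, 15), n_active = c(2, 2, 1, 15),
                   ef = c(0.5, 1.5, 0.9, 1.8),
                   ef_exact = c(0.5, 1.5, 0.9, 1.8))
  st$member_ids <- list("x", "y", "z", "w")
  sel <- select_representative(st)
  expect_setequal(sel$scaffold_smiles, c("A", "B", "D"))
  expect_equal(sel$scaffold_smiles[1], "D")  # ranked by EF desc
  expect_false("C" %in% sel$scaffold_smiles)
})

test_that("skeleton grouping merges scaffolds and honours manual merges", {
  fx <- fixture_clean()
  st <- scaffold_table(fx$records, scaffolds = fixture_scaffolds(),
                       skeletons = fixture_skeletons())
  grp <- group_by_skeleton(st)
  # groups partition the scaffold rows
  idx <- sort(unlist(lapply(grp, `[[`, "scaffold_idx")))
  expect_equal(idx, seq_len(nrow(st)))
  # every group is skeleton-pure
  expect_true(all(vapply(grp, function(g) length(g$skeletons) == 1,
                         logical(1))))
  # manual merge overrides
  grp2 <- group_by_skeleton(st, manual_groups = list(c(1, 4)))
  expect_setequal(grp2[[1]]$scaffold_idx, c(1, 4))
  expect_error(group_by_skeleton(st, manual_groups = list(c(1, 99))),
               "unknown")
  expect_error(group_by_skeleton(st, manual_groups = list(1, c(1, 2))),
               "overlap")
})

test_that("skeleton groups recover the generator's scaffold assignment", {
  fx <- fixture_clean()
  truth <- fx$truth$compounds
  st <- scaffold_table(fx$records, scaffolds = fixture_scaffolds(),
                       skeletons = fixture_skeletons())
  # each generator template maps to exactly one observed scaffold
  tpl_of <- function(ids) unique(truth$scaffold[match(ids,
                                                      truth$compound_id)])
  per_scaffold <- lapply(st$member_ids, tpl_of)
  expect_true(all(lengths(per_scaffold) == 1))
  expect_equal(length(unique(unlist(per_scaffold))), nrow(st))
})

test_that("R-group decomposition lists substituents by core position", {
  rg <- rgroup_decompose(c("Cc1ccccc1", "c1ccccc1", "Cc1ccccc1C",
                           "CCCCCC"),
                         "c1ccccc1")
  expect_equal(attr(rg, "unmatched"), "CCCCCC")
  tol <- rg[rg$compound_id == "Cc1ccccc1", ]
  expect_equal(nrow(tol), 1)
  expect_equal(tol$substituent, canonical_smiles("C"))
  expect_equal(tol$position, "R1")
  # unsubstituted member: single all-hydrogen row
  benz <- rg[rg$compound_id == "c1ccccc1", ]
  expect_equal(benz$substituent, "")
  # disubstituted member yields two attachment entries
  xyl <- rg[rg$compound_id == "Cc1ccccc1C", ]
  expect_equal(nrow(xyl), 2)
  expect_error(rgroup_decompose("Cc1ccccc1", "not_a_smiles"), "valid")
  expect_error(rgroup_decompose("Cc1ccccc1", "CCC"), "ring")
})
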