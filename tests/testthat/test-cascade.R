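test_that("upregulation filter applies strict boundaries", {
  de <- tibble::tibble(
    gene = paste0("g", 1:6),
    log2fc = c(1.2, -2, 0.5, 0, 3, 0.1),
    p = rep(0.001, 6),
    padj = c(0.01, 0.01, 0.05, 0.01, 0.002, 0.2)
  )
  expect_setequal(select_upregulated(de), c("g1", "g5"))
  # padj exactly at alpha is excluded; downregulated excluded; lfc 0 excluded
  expect_false("g3" %in% select_upregulated(de))
  expect_false("g2" %in% select_upregulated(de))
  expect_false("g4" %in% select_upregulated(de))
  expect_error(select_upregulated(de[0, ]), "empty")
})

test_that("screen dropout rule uses the guide median with an inclusive cut", {
  scr <- tibble::tibble(
    gene = c(rep("a", 3), rep("b", 2), "c"),
    guide = paste0("gd", 1:6),
    log2fc = c(-1.5, -1.2, -0.8, -0.9, -0.9, -1.0)
  )
  out <- screen_dropouts(scr, fold = 2)
  expect_true("a" %in% out)       # median -1.2 <= -1
  expect_false("b" %in% out)      # median -0.9 > -1
  expect_true("c" %in% out)       # single guide exactly -1: twofold or more
  expect_error(screen_dropouts(scr, fold = 1), "exceed 1")
})

test_that("surface filter and blacklist reproduce the fixture audit counts", {
  fx <- cascade_fixture()
  expect_equal(nrow(fx$candidates), 38)
  expect_equal(length(fx$blacklist), 16)

  sf <- surface_filter(fx$candidates$gene, fx$atlas, fx$blacklist)
  expect_equal(length(sf$kept), 22)
  expect_equal(length(sf$removed), 16)

  no_bl <- surface_filter(fx$candidates$gene, fx$atlas, character())
  expect_setequal(no_bl$kept, fx$candidates$gene)

  off_atlas <- surface_filter(c("NOTSURFACE", fx$candidates$gene[1]),
                              fx$atlas, fx$blacklist)
  expect_false("NOTSURFACE" %in% off_atlas$kept)
})

test_that("disease categorization is plain set algebra", {
  cats <- categorize(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(cats$gene[cats$category == "both"], c("B", "C"))
  expect_equal(cats$gene[cats$category == "bcCML_only"], "A")
  expect_equal(cats$gene[cats$category == "AML_only"], "D")

  disjoint <- categorize(c("A"), c("B"))
  expect_equal(sum(disjoint$category == "both"), 0)

  same <- categorize(c("A", "B"), c("A", "B"))
  expect_true(all(same$category == "both"))
})

test_that("ligand-based exclusion separates the printed reasons", {
  fx <- cascade_fixture()
  sf <- surface_filter(fx$candidates$gene, fx$atlas, fx$blacklist)
  lig <- exclude_by_ligand(sf$kept, fx$lr, fx$calls)
  expect_equal(sum(lig$exclusion_reason == "no_known_ligand"), 3)
  expect_equal(sum(lig$exclusion_reason == "no_enriched_ligand"), 4)
  expect_equal(sum(lig$exclusion_reason == "none"), 15)
  expect_setequal(lig$gene[lig$exclusion_reason == "no_known_ligand"],
                  c("MR1", "TMCO3", "TSPAN15"))
  expect_setequal(lig$gene[lig$exclusion_reason == "no_enriched_ligand"],
                  c("LGALS3BP", "CD96", "CD274", "CD3D"))

  # one enriched ligand in one population is enough to survive
  one <- exclude_by_ligand("R", tibble::tibble(ligand = "L", receptor = "R"),
                           tibble::tibble(ligand = "L", population = "MSC"))
  expect_equal(one$exclusion_reason, "none")

  # empty interaction table excludes everything as ligand-less
  empty <- exclude_by_ligand(c("R1", "R2"),
                             tibble::tibble(ligand = character(),
                                            receptor = character()),
                             fx$calls)
  expect_true(all(empty$exclusion_reason == "no_known_ligand"))
})

test_that("the synthetic cascade conserves the ledger and recovers planted receptors", {
  cfg <- synth_config(seed = 21)
  study <- simulate_study(cfg)
  rep <- run_all(study)
  ledger <- rep$ledger

  # conservation identity
  expect_equal(nrow(ledger),
               sum(ledger$survivor) + sum(ledger$exclusion_reason != "none"))

  # planted receptors survive; planted categories are respected
  planted <- cfg$planted_receptors
  expect_true(all(planted$gene %in% ledger$gene))
  expect_true(all(ledger$survivor[match(planted$gene, ledger$gene)]))
  cat_of <- ledger$category[match(planted$gene, ledger$gene)]
  expected_cat <- c(both = "both", AML = "AML_only", bcCML = "bcCML_only")
  expect_equal(cat_of, unname(expected_cat[planted$disease]))

  # blacklisted and ligand-less planted genes carry their exclusion reasons
  expect_true(all(ledger$exclusion_reason[match(cfg$blacklist_genes,
                                                ledger$gene)] == "misannotated"))
  expect_true(all(ledger$exclusion_reason[match(cfg$ligandless_receptors,
                                                ledger$gene)] == "no_known_ligand"))
  expect_true(all(ledger$exclusion_reason[match(cfg$nonenriched_receptors,
                                                ledger$gene)] == "no_enriched_ligand"))

  # cascade order invariance where commutative
  up <- select_upregulated(rep$de$bcCML)
  atlas <- cfg$atlas_genes
  expect_setequal(intersect(up, atlas), intersect(atlas, up))
})
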