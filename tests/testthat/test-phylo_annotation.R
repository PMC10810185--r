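test_that("lineage labels are the deepest shared taxon", {
  lin <- toy_lineages()
  tree <- ape::read.tree(text = "((Human,Mouse),(Fly,Worm));")
  out <- add_lineage(tree, lin)
  labels <- setNames(out$node.label, NULL)
  # nodes in ape order: root, (Human,Mouse), (Fly,Worm)
  expect_equal(labels, c("Metazoa", "Mammalia", "Metazoa"))

  mixed <- ape::read.tree(text = "((Human,Fly),Yeast);")
  out2 <- add_lineage(mixed, lin)
  expect_equal(out2$node.label, c("Eukaryota", "Metazoa"))

  # single-species clades get the species-level taxon
  dup <- ape::read.tree(text = "((HumanA,HumanB),Mouse);")
  spp <- c(HumanA = "Human", HumanB = "Human", Mouse = "Mouse")
  out3 <- add_lineage(dup, lin, tip_species = spp)
  expect_equal(out3$node.label[2], "Homo")

  expect_error(add_lineage(ape::read.tree(text = "(Human,Alien);"), lin),
               "Alien")
})

test_that("lineage labels match the set-intersection oracle on random trees", {
  lin <- random_taxonomy(30, seed = 80)
  for (rep in 1:4) {
    set.seed(80 + rep)
    tree <- ape::rtree(50)
    spp <- setNames(sample(names(lin), 50, replace = TRUE), tree$tip.label)
    out <- add_lineage(tree, lin, tip_species = spp)
    sets <- ape::prop.part(tree)
    nt <- length(tree$tip.label)
    for (i in seq_len(tree$Nnode)) {
      node_spp <- unique(spp[tree$tip.label[sets[[i]]]])
      expect_equal(out$node.label[i], oracle_lineage_lca(lin[node_spp]),
                   info = sprintf("rep %d node %d", rep, i))
    }
  }
})

test_that("lineage labels are monotone from root to tips", {
  lin <- random_taxonomy(20, seed = 85)
  set.seed(85)
  tree <- ape::rtree(30)
  spp <- setNames(sample(names(lin), 30, replace = TRUE), tree$tip.label)
  out <- add_lineage(tree, lin, tip_species = spp)
  nt <- length(tree$tip.label)
  internal <- tree$edge[, 2] > nt
  for (e in which(internal)) {
    parent_lab <- out$node.label[tree$edge[e, 1] - nt]
    child_lab <- out$node.label[tree$edge[e, 2] - nt]
    # the parent's taxon must be an ancestor-or-equal of the child's: it
    # appears in the lineage of every species under the child
    child_tips <- ape::prop.part(tree)[[tree$edge[e, 2] - nt]]
    child_spp <- unique(spp[tree$tip.label[child_tips]])
    expect_true(all(vapply(lin[child_spp],
                           function(l) parent_lab %in% l, logical(1))))
  }
})

test_that("duplication nodes require more than one shared species", {
  spp4 <- c(HumanA = "Human", MouseA = "Mouse", HumanB = "Human",
            MouseB = "Mouse")
  t1 <- ape::read.tree(text = "((HumanA,MouseA),(HumanB,MouseB));")
  d1 <- label_duplication_nodes(t1, tip_species = spp4)
  expect_equal(d1$duplication, c(TRUE, FALSE, FALSE))  # root only

  t2 <- ape::read.tree(text = "((Human,Mouse),(Fly,Worm));")
  d2 <- label_duplication_nodes(t2)
  expect_false(any(d2$duplication))

  # exactly one shared species: NOT a duplication under the >1 rule,
  # but flagged under the classical any-overlap rule
  spp3 <- c(HumanA = "Human", Mouse = "Mouse", HumanB = "Human",
            Worm = "Worm")
  t3 <- ape::read.tree(text = "((HumanA,Mouse),(HumanB,Worm));")
  d3 <- label_duplication_nodes(t3, tip_species = spp3)
  expect_false(any(d3$duplication))
  d3_loose <- label_duplication_nodes(t3, tip_species = spp3, min_shared = 1)
  expect_equal(d3_loose$duplication, c(TRUE, FALSE, FALSE))
})

test_that("min_shared = 1 flags a superset and flags are child-order invariant", {
  lin <- random_taxonomy(10, seed = 88)
  set.seed(88)
  tree <- ape::rtree(20)
  spp <- setNames(sample(names(lin), 20, replace = TRUE), tree$tip.label)
  strict <- label_duplication_nodes(tree, tip_species = spp)$duplication
  loose <- label_duplication_nodes(tree, tip_species = spp,
                                   min_shared = 1)$duplication
  expect_true(all(loose[strict]))

  swapped <- ape::read.tree(text = "((MouseB,HumanB),(MouseA,HumanA));")
  spp4 <- c(HumanA = "Human", MouseA = "Mouse", HumanB = "Human",
            MouseB = "Mouse")
  ds <- label_duplication_nodes(swapped, tip_species = spp4)
  expect_equal(ds$duplication, c(TRUE, FALSE, FALSE))
})

test_that("annotated trees round-trip node labels through newick", {
  lin <- toy_lineages()
  tree <- ape::read.tree(text = "((Human,Mouse),(Fly,Worm));")
  tree <- add_lineage(tree, lin)
  tree <- label_duplication_nodes(tree)
  path <- tempfile(fileext = ".nwk")
  write_annotated_newick(tree, path)
  back <- ape::read.tree(path)
  expect_equal(back$node.label, c("Metazoa", "Mammalia", "Metazoa"))
})

test_that("presence/absence matrix and clade summaries", {
  species <- c("Human", "Mouse", "Fly", "Worm", "Yeast", "Plant")
  hits <- data.frame(
    species = c("Human", "Human", "Mouse", "Fly", "Worm", "Yeast",
                "Human", "Mouse", "Fly", "Worm", "Yeast", "Plant"),
    gene = c(rep("XPA", 6), rep("XPC", 6)))
  pm <- presence_absence(species, hits)
  expect_equal(unname(colSums(pm)), c(5L, 6L))
  expect_false(pm["Plant", "XPA"])  # designed loss
  expect_true(pm["Plant", "XPC"])

  summ <- clade_presence_summary(pm, list(
    Animals = c("Human", "Mouse", "Fly", "Worm"),
    Other = c("Yeast", "Plant")))
  expect_equal(summ$present[summ$clade == "Animals" & summ$gene == "XPA"], 4)
  expect_equal(summ$present[summ$clade == "Other" & summ$gene == "XPA"], 1)
  expect_equal(summ$total[summ$clade == "Other"], c(2, 2))

  empty <- presence_absence(species, hits[0, ])
  expect_false(any(empty))
  expect_warning(
    presence_absence(c("Human"), data.frame(species = "Martian",
                                            gene = "XPA")),
    "Martian")
})

test_that("signature positions map through reference gaps", {
  msa <- c(ref = "C-CC", other = "CACC")
  out <- signature_conservation(msa, "ref", positions = 1:3)
  expect_equal(out$columns, c(1L, 3L, 4L))
  expect_true(out$pass[["ref"]])
  expect_error(signature_conservation(msa, "ref", positions = 1:5),
               "beyond the reference")
  expect_error(signature_conservation(msa, "nope", positions = 1), "not found")
})

test_that("designed non-homologs lacking the cysteines fail the signature", {
  set.seed(90)
  # reference: 30 residues with cysteines at 5, 12, 20; some rows gapped
  template <- strsplit("AAAAKCAAAAAKCAAAAAAKCAAAAAAAAA", "")[[1]]
  cys_pos <- which(template == "C")
  rows <- list(ref = paste(template, collapse = ""))
  for (i in 1:7) {  # true homologs: keep the cysteines, vary the rest
    r <- template
    mut <- sample(setdiff(seq_along(r), cys_pos), 6)
    r[mut] <- sample(c("G", "S", "V", "L"), 6, replace = TRUE)
    rows[[paste0("hom", i)]] <- paste(r, collapse = "")
  }
  for (i in 1:2) {  # non-homologs: no cysteines at the signature positions
    r <- template
    r[cys_pos] <- "A"
    rows[[paste0("bad", i)]] <- paste(r, collapse = "")
  }
  msa <- unlist(rows)
  out <- signature_conservation(msa, "ref", positions = cys_pos,
                                pass_fraction = 0.7)
  expect_setequal(names(out$pass)[!out$pass], c("bad1", "bad2"))
  expect_equal(unname(out$column_conservation), rep(8 / 10, 3))
})

test_that("lineage TSV parses into root-first lineages", {
  p <- write_tmp(c("Human\tEukaryota;Metazoa;Chordata;Mammalia;Homo",
                   "Fly\tEukaryota;Metazoa;Arthropoda;Drosophila"))
  lin <- read_lineage_tsv(p)
  expect_equal(lin$Human[4], "Mammalia")
  expect_length(lin$Fly, 4)
  expect_error(read_lineage_tsv(write_tmp("Human only")), "line 1")
})
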