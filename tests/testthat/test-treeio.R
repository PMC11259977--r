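test_that("Newick parsing builds valid trees and round-trips", {
  tt <- parse_newick("((A,B),C);")
  expect_equal(ape::Ntip(tt$phy), 3L)
  expect_equal(tt$phy$Nnode, 2L)
  kids <- tt$phy$edge[tt$phy$edge[, 1] == 4L, 2]
  expect_true(any(kids <= 3))

  tt2 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_false(anyNA(tt2$ages))
  expect_equal(unname(tt2$ages[4L]), 2) # root age = tip depth
  rt <- parse_newick(write_newick(tt2))
  expect_true(ape::all.equal.phylo(rt$phy, tt2$phy, use.edge.length = FALSE))
  expect_equal(rt$ages, tt2$ages, tolerance = 1e-9)

  two <- parse_newick("(A:3,B:3);")
  expect_match(write_newick(two), "^\\(A:3,B:3\\);$")
})

test_that("malformed Newick is rejected with informative errors", {
  expect_error(parse_newick("((A,B),C;"), "unbalanced")
  expect_error(parse_newick("((A,B),A);"), "duplicate leaf label: A")
  expect_error(parse_newick("((A,B,C),D);"), "non-binary")
  res <- parse_newick("((A,B,C),D);", strict = FALSE)
  expect_true(ape::is.binary(res$phy))
})

test_that("dated round-trips preserve topology, labels and ages", {
  for (s in 1:5) {
    set.seed(s)
    phy <- ape::rcoal(6 + s)
    tt <- parse_newick(ape::write.tree(phy))
    rt <- parse_newick(write_newick(tt))
    expect_true(ape::all.equal.phylo(rt$phy, tt$phy,
                                     use.edge.length = FALSE))
    expect_equal(rt$ages, tt$ages, tolerance = 1e-6)
    expect_true(all(branch_durations(tt) >= 0))
  }
})

test_that("duplicated topology mirrors the WGD clade below a new node", {
  dup <- fish_duplicated()
  expect_equal(ape::Ntip(dup$phy), 18L) # 6 x 2 + 6
  wgd <- attr(dup, "wgd_node")
  expect_equal(dup$phy$node.label[wgd - 18L], "WGD")
  # the two children of the WGD node are topologically identical copies
  kids <- dup$phy$edge[dup$phy$edge[, 1] == wgd, 2]
  subs <- lapply(kids, function(k) {
    s <- ape::extract.clade(dup$phy, k)
    s$tip.label <- sub("_[12]$", "", s$tip.label)
    s
  })
  expect_equal(phangorn::RF.dist(subs[[1]], subs[[2]]), 0)
  # the crown node of the duplicated clade exists once per copy
  crown1 <- ape::getMRCA(dup$phy, c("Scleropages_1", "Takifugu_1"))
  crown2 <- ape::getMRCA(dup$phy, c("Scleropages_2", "Takifugu_2"))
  expect_false(crown1 == crown2)
  expect_true(all(c(crown1, crown2) != wgd))

  # leaf-count arithmetic holds for any clade choice
  sp <- fish_species_tree()
  for (clade in list(c("Gasterosteus", "Takifugu"),
                     c("Danio", "Esox", "Gasterosteus", "Takifugu"))) {
    d <- build_duplicated_topology(sp, clade)
    expect_equal(ape::Ntip(d$phy), 12L - length(clade) + 2L * length(clade))
  }
})

test_that("duplicated topology rejects bad inputs", {
  sp <- fish_species_tree()
  expect_error(build_duplicated_topology(sp, c("Danio", "Amia")),
               "not monophyletic")
  expect_error(build_duplicated_topology(sp, sp$phy$tip.label),
               "outside")
  sp2 <- parse_newick("((A,B),(C,C_1));")
  expect_error(build_duplicated_topology(sp2, "C"), "collision")
})

test_that("conformance screen accepts matching gene trees", {
  dup <- fish_duplicated()
  v <- screen_orthogroup(timetree(dup$phy), dup)
  expect_true(v$pass)

  # missing one outgroup taxon: still conformant after pruning
  g <- ape::drop.tip(dup$phy, "Polyodon")
  expect_true(screen_orthogroup(timetree(g), dup)$pass)

  # globally swapped copy suffixes: invariant
  g2 <- dup$phy
  g2$tip.label <- ifelse(grepl("_1$", g2$tip.label),
                         sub("_1$", "_2", g2$tip.label),
                         sub("_2$", "_1", g2$tip.label))
  expect_true(screen_orthogroup(timetree(g2), dup)$pass)

  # leaf-order permutation: invariant (rotate a clade)
  g3 <- ape::read.tree(text = ape::write.tree(ape::rotate(dup$phy, 20L)))
  expect_true(screen_orthogroup(timetree(g3), dup)$pass)
})

test_that("conformance screen rejects lineage-specific duplications", {
  dup <- fish_duplicated()
  # build a gene tree in which Danio_1 and Danio_2 are sisters
  g <- ape::drop.tip(dup$phy, "Danio_2")
  txt <- sub("Danio_1", "(Danio_1,Danio_2)", ape::write.tree(g),
             fixed = TRUE)
  g <- ape::read.tree(text = txt)
  expect_true(all(c("Danio_1", "Danio_2") %in% g$tip.label))
  v <- screen_orthogroup(timetree(g), dup)
  expect_false(v$pass)
  expect_match(v$reason, "conflict|uninformative")
})

test_that("conformance screen flags unrootable and uninformative loci", {
  dup <- fish_duplicated()
  og <- study_design()$outgroup_taxa
  g <- ape::drop.tip(dup$phy, og)
  expect_error(screen_orthogroup(timetree(g), dup), "unrootable")
  # a single taxon left in one mirrored copy
  g2 <- ape::drop.tip(dup$phy,
                      paste0(setdiff(study_design()$duplicated_taxa,
                                     "Danio"), "_2"))
  v <- screen_orthogroup(timetree(g2), dup)
  expect_false(v$pass)
  expect_match(v$reason, "uninformative")
})

test_that("locus filtering reproduces the design counts", {
  roster <- fish_duplicated()$phy$tip.label
  mkseq <- function(n, len) {
    s <- vapply(seq_len(n), function(i)
      paste(rep("A", len), collapse = ""), character(1))
    names(s) <- roster[seq_len(n)]
    s
  }
  loci <- lapply(1:30, function(i) locus_alignment(paste0("L", i),
                                                   mkseq(18, 100 + i)))
  # delete one gene from each of three loci
  for (i in 1:3) {
    s <- loci[[i]]$seqs[-i]
    loci[[i]] <- locus_alignment(loci[[i]]$id, s)
  }
  os <- filter_and_concatenate(loci, min_len = 100, roster = roster)
  expect_equal(os$summary$n_loci, 30L)
  expect_equal(os$summary$n_sequences_total, 537L) # 30 x 18 - 3
  expect_equal(os$summary$n_complete_loci, 27L)
  # brute-force recount
  expect_equal(os$summary$n_columns_total,
               sum(vapply(os$loci, function(l) l$n_sites, integer(1))))

  short <- locus_alignment("short", mkseq(18, 90))
  os2 <- filter_and_concatenate(c(loci, list(short)), roster = roster)
  expect_equal(os2$summary$n_loci, 30L) # 90-column locus discarded
  expect_error(filter_and_concatenate(list(short)), "no loci pass")
  expect_error(filter_and_concatenate(list()), "no loci")
})

test_that("FASTA and calibration-table IO round-trip", {
  aln <- locus_alignment("x", c(A = "ARND-", B = "AR??D"))
  p <- tempfile(fileext = ".fasta")
  write_locus_fasta(aln, p)
  back <- read_locus_fasta(p, "x")
  expect_equal(back$seqs, aln$seqs)

  tab <- data.frame(clade_label = "root", taxonA = "Polypterus",
                    taxonB = "Amia", min_Ma = 365, max_Ma = 425)
  tp <- tempfile(fileext = ".tsv")
  write.table(tab, tp, sep = "\t", row.names = FALSE, quote = FALSE)
  tab2 <- read_calibration_table(tp)
  expect_equal(tab2$min_Ma, 365)
  cal <- calibrations_for_tree(fish_duplicated(), tab2)
  expect_equal(names(cal), "19") # root of the 18-tip tree
  expect_equal(cal[["19"]]$t_min, 3.65)
})
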