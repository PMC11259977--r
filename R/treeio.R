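#' Time-calibrated tree container
#'
#' A light wrapper around an [ape::phylo] object that carries node ages.
#' Ages are stored in units of 100 Myr (the numerical conditioning
#' convention of clock-dating software); all user-facing tables are in Ma.
#' Node indexing follows the `phylo` convention: tips `1..Ntip`, root
#' `Ntip + 1`, further internal nodes above that. Tip ages are 0.
#'
#' @param phy A rooted, binary `phylo` object.
#' @param ages Optional numeric vector of node ages (100 Myr), length
#'   `Ntip + Nnode`; tips must be 0. If omitted, internal ages are `NA`.
#' @return An object of class `timetree`: a list with elements `phy` and
#'   `ages`.
#' @export
timetree <- function(phy, ages = NULL) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape 'phylo' object")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("non-binary tree: resolve polytomies first")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  n_all <- ape::Ntip(phy) + phy$Nnode
  if (is.null(ages)) {
    ages <- rep(NA_real_, n_all)
    ages[seq_len(ape::Ntip(phy))] <- 0
  }
  if (length(ages) != n_all) stop("'ages' must have one entry per node")
  tt <- structure(list(phy = phy, ages = ages), class = "timetree")
  validate_ages(tt)
  tt
}

validate_ages <- function(tt) {
  a <- tt$ages
  if (all(is.na(a[-seq_len(ape::Ntip(tt$phy))]))) return(invisible(tt))
  if (anyNA(a)) stop("ages must be assigned for all nodes or none")
  d <- a[tt$phy$edge[, 1]] - a[tt$phy$edge[, 2]]
  if (any(d < -1e-9)) stop("child age exceeds parent age")
  if (any(abs(a[seq_len(ape::Ntip(tt$phy))]) > 1e-9)) stop("tip ages must be 0")
  invisible(tt)
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree:", ape::Ntip(x$phy), "tips,", x$phy$Nnode, "internal nodes")
  ra <- x$ages[ape::Ntip(x$phy) + 1L]
  if (!is.na(ra)) cat(", root age", format(unit_to_ma(ra)), "Ma")
  cat("\n")
  invisible(x)
}

n_tips <- function(tt) ape::Ntip(tt$phy)
root_node <- function(tt) ape::Ntip(tt$phy) + 1L
internal_nodes <- function(tt) root_node(tt) + 0:(tt$phy$Nnode - 1L)

#' Branch durations of a dated tree
#'
#' @param tt A `timetree` with ages assigned.
#' @return Numeric vector of parent-minus-child age differences (100 Myr),
#'   one per row of `tt$phy$edge`.
#' @export
branch_durations <- function(tt) {
  stopifnot(inherits(tt, "timetree"))
  tt$ages[tt$phy$edge[, 1]] - tt$ages[tt$phy$edge[, 2]]
}

#' Canonical branch ordering
#'
#' All branch-length vectors (clock expectations, likelihood approximations,
#' BV files) follow one deterministic ordering: the rows of the edge matrix
#' after [ape::reorder.phylo] into postorder. Each branch is identified by
#' its child node.
#'
#' @param phy A `phylo` object or `timetree`.
#' @return The edge matrix (parent, child) in canonical order.
#' @export
canonical_edges <- function(phy) {
  if (inherits(phy, "timetree")) phy <- phy$phy
  ape::reorder.phylo(phy, "postorder")$edge
}

#' Parse a Newick string into a timetree
#'
#' Branch lengths, when present and ultrametric, are interpreted as time and
#' converted to node ages; otherwise the tree is kept as an (undated)
#' topology with its original edge lengths (e.g. a gene tree in
#' substitutions/site).
#'
#' @param text A Newick string.
#' @param strict If `TRUE` (default) polytomies are rejected; otherwise they
#'   are resolved deterministically (left-first, zero-length) via
#'   [ape::multi2di] with `random = FALSE`.
#' @return A `timetree`.
#' @export
parse_newick <- function(text, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick: ", n_open, " '(' vs ", n_close, " ')'")
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1L])
  if (!ape::is.rooted(phy)) phy <- ape::unroot(phy) # normalize before check
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    if (strict && !ape::is.binary(phy))
      stop("non-binary tree (polytomy); use strict = FALSE to binarize")
    phy <- ape::multi2di(phy, random = FALSE)
  }
  ages <- NULL
  if (!is.null(phy$edge.length)) {
    dep <- ape::node.depth.edgelength(phy)
    tipdep <- dep[seq_len(ape::Ntip(phy))]
    if (diff(range(tipdep)) <= 1e-6 * max(tipdep, 1)) {
      ages <- max(tipdep) - dep
      ages[seq_len(ape::Ntip(phy))] <- 0
    }
  }
  timetree(phy, ages)
}

#' Write a timetree as Newick
#'
#' If ages are assigned, branch lengths are emitted as parent-minus-child
#' age differences so that the string re-parses to the same chronogram.
#'
#' @param tt A `timetree`.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tt, digits = 10) {
  stopifnot(inherits(tt, "timetree"))
  phy <- tt$phy
  if (!anyNA(tt$ages)) phy$edge.length <- branch_durations(tt)
  ape::write.tree(phy, digits = digits)
}

#' Build the duplicated ("mirrored") topology below a WGD node
#'
#' The subtree spanned by `wgd_clade` is duplicated and its two copies are
#' attached as sisters under a new node (the WGD node); leaves of the copies
#' carry the two suffixes. Backbone relationships are untouched. Mirrored
#' speciation nodes exist in both copies and are dated independently
#' downstream.
#'
#' @param species A `timetree` or `phylo` species tree (topology is used).
#' @param wgd_clade Character vector of taxa forming the duplicated clade;
#'   must be monophyletic and a proper subset of the taxa.
#' @param copy_suffixes Length-2 character vector of ohnologue-copy suffixes.
#' @return A `timetree` (undated) whose WGD node carries the node label
#'   `"WGD"`; the node id is also in attribute `wgd_node`.
#' @export
build_duplicated_topology <- function(species, wgd_clade,
                                      copy_suffixes = c("_1", "_2")) {
  phy <- if (inherits(species, "timetree")) species$phy else species
  phy$edge.length <- NULL
  phy$node.label <- NULL
  tips <- phy$tip.label
  if (!all(wgd_clade %in% tips))
    stop("wgd_clade taxa absent from species tree: ",
         paste(setdiff(wgd_clade, tips), collapse = ", "))
  if (length(setdiff(tips, wgd_clade)) == 0L)
    stop("wgd_clade must leave at least one taxon outside the duplication")
  if (length(copy_suffixes) != 2L || copy_suffixes[1] == copy_suffixes[2])
    stop("copy_suffixes must be two distinct strings")
  new_tips <- as.vector(outer(wgd_clade, copy_suffixes, paste0))
  if (any(new_tips %in% tips))
    stop("suffix collision: ", paste(intersect(new_tips, tips), collapse = ", "))
  if (length(wgd_clade) > 1L && !ape::is.monophyletic(phy, wgd_clade))
    stop("wgd_clade is not monophyletic in the species tree")

  strip <- function(p) sub(";$", "", ape::write.tree(p))
  if (length(wgd_clade) == 1L) {
    sub_txt <- wgd_clade
  } else {
    sub_phy <- ape::extract.clade(phy, ape::getMRCA(phy, wgd_clade))
    sub_txt <- strip(sub_phy)
  }
  suffixed <- function(txt, suf) {
    # append suffix to each clade taxon name within the subtree string
    for (tx in wgd_clade)
      txt <- gsub(paste0("(?<![A-Za-z0-9_.])", tx, "(?![A-Za-z0-9_.])"),
                  paste0(tx, suf), txt, perl = TRUE)
    txt
  }
  dup_txt <- paste0("(", suffixed(sub_txt, copy_suffixes[1]), ",",
                    suffixed(sub_txt, copy_suffixes[2]), ")")
  keep1 <- wgd_clade[1]
  backbone <- if (length(wgd_clade) > 1L)
    ape::drop.tip(phy, setdiff(wgd_clade, keep1)) else phy
  placeholder <- "zzWGDPLACEHOLDERzz"
  backbone$tip.label[backbone$tip.label == keep1] <- placeholder
  out_txt <- sub(placeholder, dup_txt, strip(backbone), fixed = TRUE)
  out <- ape::read.tree(text = paste0(out_txt, ";"))
  wgd_node <- ape::getMRCA(out, new_tips)
  out$node.label <- rep("", out$Nnode)
  out$node.label[wgd_node - ape::Ntip(out)] <- "WGD"
  tt <- timetree(out)
  attr(tt, "wgd_node") <- wgd_node
  attr(tt, "wgd_clade") <- wgd_clade
  attr(tt, "copy_suffixes") <- copy_suffixes
  tt
}

clade_strings <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  vapply(pp, function(i) paste(sort(labs[i]), collapse = "|"), character(1))
}

#' Screen an orthogroup gene tree for WGD conformance
#'
#' A gene tree conforms when, after rooting on the non-duplicated outgroup
#' and pruning taxa missing from the gene tree, its rooted topology equals
#' the correspondingly pruned duplicated topology under some assignment of
#' each taxon's two gene copies to the two mirrored subtrees (gene trees do
#' not label which ohnologue is which, so both assignments are tried per
#' taxon). This automates the divergence-before-speciation criterion as a
#' strict rooted topology match.
#'
#' @param gene A `timetree` or `phylo` gene tree. Tip labels are outgroup
#'   taxon names, or duplicated-clade taxon names carrying one of the two
#'   copy suffixes.
#' @param expected Output of [build_duplicated_topology()].
#' @param min_outgroup,min_copy_taxa Informativeness thresholds: minimum
#'   outgroup taxa present, and minimum taxa present in each mirrored copy.
#' @return A list with `pass` (logical), `reason` (character), and, when
#'   passing, the copy `assignment` used.
#' @export
screen_orthogroup <- function(gene, expected, min_outgroup = 1L,
                              min_copy_taxa = 2L) {
  gphy <- if (inherits(gene, "timetree")) gene$phy else gene
  ephy <- expected$phy
  suf <- attr(expected, "copy_suffixes")
  wgd_taxa <- attr(expected, "wgd_clade")
  if (is.null(suf) || is.null(wgd_taxa))
    stop("'expected' must come from build_duplicated_topology()")
  outgroup <- setdiff(ephy$tip.label,
                      as.vector(outer(wgd_taxa, suf, paste0)))

  gt <- gphy$tip.label
  bad <- setdiff(gt, c(outgroup, as.vector(outer(wgd_taxa, suf, paste0))))
  if (length(bad))
    stop("gene-tree labels not in the expected roster: ",
         paste(bad, collapse = ", "))
  og_present <- intersect(gt, outgroup)
  if (length(og_present) == 0L)
    stop("unrootable: gene tree retains no outgroup taxon")
  if (length(og_present) < min_outgroup)
    return(list(pass = FALSE,
                reason = sprintf("uninformative: %d outgroup taxa (< %d)",
                                 length(og_present), min_outgroup)))
  # taxa with each copy present
  cp1 <- wgd_taxa[paste0(wgd_taxa, suf[1]) %in% gt]
  cp2 <- wgd_taxa[paste0(wgd_taxa, suf[2]) %in% gt]
  if (min(length(cp1), length(cp2)) < min_copy_taxa)
    return(list(pass = FALSE,
                reason = sprintf(
                  "uninformative: a mirrored copy retains %d taxa (< %d)",
                  min(length(cp1), length(cp2)), min_copy_taxa)))

  # The outgroup taxa are typically paraphyletic with respect to the
  # duplicated clade, so orientation is fixed by rerooting both trees on
  # the same single outgroup leaf before comparing rooted clade sets.
  anchor <- outgroup[outgroup %in% og_present][1]
  rooted <- tryCatch(
    ape::root(ape::unroot(gphy), outgroup = anchor, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted))
    return(list(pass = FALSE, reason = "gene tree could not be rooted"))
  rooted$edge.length <- NULL

  taxa_present <- union(cp1, cp2)
  n_assign <- 2L^length(taxa_present)
  first_mismatch <- NULL
  for (code in seq_len(n_assign) - 1L) {
    flip <- as.logical(bitwAnd(code, 2L^(seq_along(taxa_present) - 1L)))
    relab <- gt
    for (k in seq_along(taxa_present)) {
      tx <- taxa_present[k]
      s_from <- if (flip[k]) rev(suf) else suf
      relab[gt == paste0(tx, s_from[1])] <- paste0(tx, suf[1])
      relab[gt == paste0(tx, s_from[2])] <- paste0(tx, suf[2])
    }
    g2 <- rooted
    g2$tip.label <- relab[match(rooted$tip.label, gt)]
    epr <- ape::drop.tip(ephy, setdiff(ephy$tip.label, g2$tip.label))
    epr <- ape::root(ape::unroot(epr), outgroup = anchor,
                     resolve.root = TRUE)
    gc <- clade_strings(g2)
    ec <- clade_strings(epr)
    if (setequal(gc, ec)) {
      assignment <- stats::setNames(ifelse(flip, "swapped", "direct"),
                                    taxa_present)
      return(list(pass = TRUE, reason = "conformant", assignment = assignment))
    }
    if (is.null(first_mismatch)) {
      off <- setdiff(gc, ec)
      first_mismatch <- off[which.min(nchar(off))]
    }
  }
  list(pass = FALSE,
       reason = paste0("topology conflict: gene-tree clade {",
                       gsub("\\|", ", ", first_mismatch),
                       "} absent from the duplicated species topology"))
}

#' Locus alignment container
#'
#' @param id Locus identifier.
#' @param seqs Named character vector of equal-length amino-acid sequences;
#'   `-` (gap) and `?`/`X` are treated as missing data downstream.
#' @return An object of class `locus_alignment` with fields `id`, `seqs`,
#'   `n_sites`.
#' @export
locus_alignment <- function(id, seqs) {
  stopifnot(is.character(seqs), length(seqs) > 0L, !is.null(names(seqs)))
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences differ in length in locus ", id)
  if (len == 0L) stop("zero-length alignment in locus ", id)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence labels in locus ", id)
  structure(list(id = as.character(id), seqs = toupper(seqs),
                 n_sites = as.integer(len)),
            class = "locus_alignment")
}

#' Read one locus from a FASTA file
#'
#' @param path FASTA file of aligned amino-acid sequences.
#' @param id Locus id; defaults to the file name without extension.
#' @return A `locus_alignment`.
#' @export
read_locus_fasta <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  aa <- ape::read.FASTA(path, type = "AA")
  seqs <- vapply(as.character(aa), paste, character(1), collapse = "")
  locus_alignment(id, seqs)
}

#' Write one locus to a FASTA file
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  con <- file(path, "wb") # fixed newline convention: byte-stable output
  on.exit(close(con))
  for (i in seq_along(aln$seqs))
    writeLines(c(paste0(">", names(aln$seqs)[i]), aln$seqs[[i]]), con,
               sep = "\n")
  invisible(path)
}

#' Filter loci and summarize the concatenated dataset
#'
#' Loci shorter than `min_len` columns are discarded. Sequence totals count
#' sequences present per retained locus (per-locus partitions are kept; no
#' supermatrix row merging).
#'
#' @param loci List of `locus_alignment` objects (already conformance
#'   screened).
#' @param min_len Minimum alignment length in columns.
#' @param roster Character vector of expected sequence labels; a locus is
#'   complete iff all are present.
#' @return An object of class `ohnologue_set`: retained `loci`,
#'   `complete` flags, and a `summary` list with `n_loci`,
#'   `n_sequences_total`, `n_columns_total`, `n_complete_loci`.
#' @export
filter_and_concatenate <- function(loci, min_len = 100L, roster = NULL) {
  if (length(loci) == 0L) stop("no loci supplied")
  stopifnot(all(vapply(loci, inherits, logical(1), "locus_alignment")))
  keep <- vapply(loci, function(l) l$n_sites >= min_len, logical(1))
  loci <- loci[keep]
  if (length(loci) == 0L) stop("no loci pass filters")
  complete <- if (is.null(roster)) rep(NA, length(loci)) else
    vapply(loci, function(l) all(roster %in% names(l$seqs)), logical(1))
  res <- structure(list(
    loci = loci,
    roster = roster,
    complete = complete,
    summary = list(
      n_loci = length(loci),
      n_sequences_total = sum(vapply(loci, function(l) length(l$seqs),
                                     integer(1))),
      n_columns_total = sum(vapply(loci, function(l) l$n_sites, integer(1))),
      n_complete_loci = if (anyNA(complete)) NA_integer_ else sum(complete))),
    class = "ohnologue_set")
  res
}

#' @export
print.ohnologue_set <- function(x, ...) {
  s <- x$summary
  cat("ohnologue_set:", s$n_loci, "loci,", s$n_sequences_total,
      "sequences,", s$n_columns_total, "columns,",
      s$n_complete_loci, "complete loci\n")
  invisible(x)
}

#' Read a tab-delimited calibration table
#'
#' Columns: `clade_label`, `taxonA`, `taxonB`, `min_Ma`, `max_Ma`. Each row
#' calibrates the most recent common ancestor of the two named taxa.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_calibration_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clade_label", "taxonA", "taxonB", "min_Ma", "max_Ma")
  if (!all(need %in% names(tab)))
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Attach calibrations from a table to tree nodes
#'
#' @param tt A `timetree`.
#' @param table Data frame as returned by [read_calibration_table()].
#' @return Named list mapping node id (as character) to [calibration()]
#'   objects (internal 100-Myr units).
#' @export
calibrations_for_tree <- function(tt, table) {
  phy <- tt$phy
  out <- list()
  for (i in seq_len(nrow(table))) {
    miss <- setdiff(c(table$taxonA[i], table$taxonB[i]), phy$tip.label)
    if (length(miss))
      stop("calibration '", table$clade_label[i], "' names unknown taxa: ",
           paste(miss, collapse = ", "))
    node <- ape::getMRCA(phy, c(table$taxonA[i], table$taxonB[i]))
    cal <- calibration(ma_to_unit(table$min_Ma[i]), ma_to_unit(table$max_Ma[i]))
    attr(cal, "label") <- table$clade_label[i]
    out[[as.character(node)]] <- cal
  }
  out
}
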