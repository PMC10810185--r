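# tip indices under every node (tips 1..Ntip, internal Ntip+1..Ntip+Nnode)
.node_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  sets <- c(as.list(seq_len(nt)), vector("list", tree$Nnode))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

.resolve_tip_species <- function(tree, tip_species) {
  if (is.null(tip_species)) {
    return(setNames(tree$tip.label, tree$tip.label))
  }
  miss <- setdiff(tree$tip.label, names(tip_species))
  if (length(miss) > 0) {
    stop("no species mapping for tip(s): ", paste(miss, collapse = ", "))
  }
  tip_species[tree$tip.label]
}

# deepest taxon shared by all lineages (positional common prefix, root first)
.lineage_lca <- function(lineages) {
  k <- min(lengths(lineages))
  depth <- 0L
  for (i in seq_len(k)) {
    taxa <- vapply(lineages, `[`, character(1), i)
    if (length(unique(taxa)) > 1) break
    depth <- i
  }
  if (depth == 0L) {
    stop("lineages share no common root taxon")
  }
  lineages[[1]][depth]
}

#' Label internal nodes with the deepest shared taxonomic level
#'
#' Every internal node is labelled with the lineage LCA of the species under
#' it: the lowest (most specific) taxonomic level common to all of the clade's
#' species, read off the root-to-species lineage vectors. Labels are monotone
#' along the tree: a node's label is an ancestor-or-equal taxon of each
#' child's label.
#'
#' @param tree an [ape] `phylo` tree.
#' @param lineages named list mapping species id to its lineage (root-first
#'   character vector), e.g. from [read_lineage_tsv()].
#' @param tip_species optional named character vector mapping tip labels to
#'   species ids (by default the tip label is the species id), for protein
#'   trees whose tips are gene/protein accessions.
#' @return the tree with `node.label` set to the lineage labels.
#' @export
add_lineage <- function(tree, lineages, tip_species = NULL) {
  spp <- .resolve_tip_species(tree, tip_species)
  missing <- setdiff(unique(spp), names(lineages))
  if (length(missing) > 0) {
    stop("no lineage for species: ", paste(missing, collapse = ", "))
  }
  roots <- vapply(lineages[unique(spp)], `[`, character(1), 1L)
  if (length(unique(roots)) > 1) {
    stop("lineages do not share a common root taxon")
  }
  nt <- length(tree$tip.label)
  sets <- .node_tip_sets(tree)
  labels <- vapply(seq_len(tree$Nnode), function(i) {
    node_spp <- unique(spp[tree$tip.label[sets[[nt + i]]]])
    .lineage_lca(lineages[node_spp])
  }, character(1))
  tree$node.label <- labels
  tree
}

#' Flag gene-duplication nodes by species overlap
#'
#' An internal node is flagged as a duplication when its child clades share at
#' least `min_shared` species: the same species appearing on both sides of a
#' split implies the split is a gene duplication, not a speciation. The
#' default `min_shared = 2` is the conservative "more than one common species"
#' rule (stricter than the classical any-overlap rule, which is one parameter
#' away as `min_shared = 1`). Multifurcating nodes are evaluated over all
#' child pairs; any qualifying pair flags the node.
#'
#' @inheritParams add_lineage
#' @param min_shared minimum number of species common to two child clades.
#' @return the tree with a logical `duplication` vector (one entry per
#'   internal node, in `node.label` order).
#' @export
label_duplication_nodes <- function(tree, tip_species = NULL,
                                    min_shared = 2L) {
  spp <- .resolve_tip_species(tree, tip_species)
  nt <- length(tree$tip.label)
  sets <- .node_tip_sets(tree)
  spp_sets <- lapply(sets, function(s) unique(spp[tree$tip.label[s]]))
  dup <- vapply(seq_len(tree$Nnode), function(i) {
    node <- nt + i
    children <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(children) < 2) return(FALSE)
    pairs <- utils::combn(length(children), 2)
    any(apply(pairs, 2, function(p) {
      length(intersect(spp_sets[[children[p[1]]]],
                       spp_sets[[children[p[2]]]])) >= min_shared
    }))
  }, logical(1))
  tree$duplication <- dup
  tree
}

#' Write an annotated tree as newick
#'
#' Node labels are the lineage labels with `|D` appended at duplication nodes.
#'
#' @param tree a `phylo` tree, optionally with `node.label` and `duplication`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(tree, path) {
  if (!is.null(tree$duplication)) {
    lab <- if (is.null(tree$node.label)) {
      rep("", tree$Nnode)
    } else tree$node.label
    tree$node.label <- paste0(lab, ifelse(tree$duplication, "|D", ""))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Species-by-gene presence/absence matrix
#'
#' @param species character vector of species ids (the rows; typically the
#'   species tree's tips).
#' @param assignments data.frame of accepted homologs with columns `species`
#'   and `gene` (one row per accepted protein). Assignments for species not in
#'   `species` are dropped with a warning.
#' @param genes optional character vector fixing the column set/order.
#' @return logical matrix, species x gene.
#' @export
presence_absence <- function(species, assignments, genes = NULL) {
  if (is.null(genes)) genes <- unique(assignments$gene)
  stray <- setdiff(unique(assignments$species), species)
  if (length(stray) > 0) {
    warning("assignments for species not in the species list dropped: ",
            paste(stray, collapse = ", "))
    assignments <- assignments[assignments$species %in% species, ]
  }
  m <- matrix(FALSE, length(species), length(genes),
              dimnames = list(species, genes))
  if (nrow(assignments) > 0) {
    m[cbind(match(assignments$species, species),
            match(assignments$gene, genes))] <- TRUE
  }
  m
}

#' Per-clade presence summaries
#'
#' @param presence matrix from [presence_absence()].
#' @param clades named list mapping clade name to its species ids.
#' @return data.frame with `clade`, `gene`, `present`, `total`.
#' @export
clade_presence_summary <- function(presence, clades) {
  do.call(rbind, lapply(names(clades), function(cl) {
    sp <- intersect(clades[[cl]], rownames(presence))
    data.frame(clade = cl, gene = colnames(presence),
               present = colSums(presence[sp, , drop = FALSE]),
               total = length(sp), row.names = NULL)
  }))
}

#' Check conservation of signature residues in an alignment
#'
#' Maps reference-sequence positions (1-based, ungapped) to alignment columns
#' through the reference row's gap structure, then scores every sequence by
#' the fraction of signature columns carrying the required residue. The
#' default signature is the conserved cysteines of the XPA family at human
#' XPA positions 105-108, 126-128 and 261-264; sequences retaining at least
#' `pass_fraction` of them are accepted as likely functional homologs.
#'
#' @param msa named character vector of aligned sequences (equal lengths; gaps
#'   `-`), e.g. `read_fasta(path, alphabet = "AA")`.
#' @param reference name of the reference row (e.g. the human protein).
#' @param positions integer vector of reference-sequence positions.
#' @param residue required residue (single letter).
#' @param pass_fraction minimum fraction of signature positions required.
#' @return list with `columns` (alignment columns of the signature),
#'   `fraction` (per-sequence fraction of signature columns matching),
#'   `pass` (named logical), `column_conservation` (per-column fraction of
#'   sequences carrying the residue).
#' @export
signature_conservation <- function(msa, reference,
                                   positions = c(105:108, 126:128, 261:264),
                                   residue = "C", pass_fraction = 0.7) {
  if (!reference %in% names(msa)) {
    stop("reference row '", reference, "' not found in the alignment")
  }
  widths <- unique(nchar(msa))
  if (length(widths) != 1) stop("alignment rows have unequal lengths")
  ref_chars <- strsplit(msa[[reference]], "", fixed = TRUE)[[1]]
  ungapped <- which(!ref_chars %in% c("-", "."))
  if (any(positions > length(ungapped))) {
    stop("signature position beyond the reference length (",
         length(ungapped), " residues)")
  }
  cols <- ungapped[positions]
  residue <- toupper(residue)
  hit <- vapply(cols, function(cc) {
    toupper(substring(msa, cc, cc)) == residue
  }, logical(length(msa)))
  hit <- matrix(hit, nrow = length(msa),
                dimnames = list(names(msa), cols))
  frac <- rowMeans(hit)
  list(columns = cols, fraction = frac, pass = frac >= pass_fraction,
       column_conservation = colMeans(hit))
}
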