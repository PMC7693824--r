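## Similarity cladogram over the peptide family: identity-based distances,
## UPGMA/NJ agglomeration (ape/phangorn), Newick export, monophyly queries.

#' Pairwise identity distance matrix
#'
#' `d = 1 - identity_fraction` from [global_align()] (identical columns over
#' total alignment length). No substitution-model correction: the cladogram
#' displays raw similarity clustering.
#'
#' @param records Catalogue-style data.frame (`name`, `sequence`) with >= 3
#'   rows and unique names.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = names.
#' @export
distance_matrix <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (anyDuplicated(records$name)) stop("duplicate labels", call. = FALSE)
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$name, records$name))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align(records$sequence[i], records$sequence[j])
      d[i, j] <- d[j, i] <- 1 - al$n_identical / al$length
    }
  }
  d
}

#' Build a similarity tree
#'
#' UPGMA (default; average-linkage agglomeration, yields an ultrametric
#' rooted cladogram) or neighbor-joining over a distance matrix.
#'
#' @param d Symmetric distance matrix with labeled dimnames, or a `dist`.
#' @param method `"upgma"` or `"nj"`.
#' @return An [ape::phylo] tree.
#' @export
build_tree <- function(d, method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("d must be symmetric with zero diagonal", call. = FALSE)
  }
  if (method == "upgma") {
    phangorn::upgma(stats::as.dist(d))
  } else {
    ape::nj(stats::as.dist(d))
  }
}

#' Is a set of leaves monophyletic?
#'
#' TRUE iff the smallest subtree (clade) containing `leaves` contains no
#' other leaves. Singletons and the full leaf set are trivially monophyletic.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaves Character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leaves) {
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing) > 0L) {
    stop("leaf/leaves not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(leaves) <= 1L || setequal(leaves, tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, leaves)
}

#' Write / read a tree as Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file.
#' @return `path` invisibly; `read_newick` returns the tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Family cladogram in one call
#'
#' @param records Catalogue-style data.frame; defaults to the 28 family
#'   members of the packaged catalogue.
#' @param method Passed to [build_tree()].
#' @return An [ape::phylo] tree.
#' @export
family_tree <- function(records = NULL, method = "upgma") {
  if (is.null(records)) {
    cat <- load_catalogue()
    records <- cat[cat$group == "family_member", ]
  }
  build_tree(distance_matrix(records), method = method)
}
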