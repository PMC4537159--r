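#' Read a newick tree
#'
#' Thin wrapper over \code{\link[ape]{read.tree}} adding the checks the
#' delimitation pipeline relies on: quoted labels, branch lengths and
#' internal support values are retained; unbalanced parentheses are
#' reported with the character offset of the first excess bracket;
#' duplicate leaf labels are an error.
#'
#' @param path newick file path.
#' @return an \code{ape} \code{phylo} object.
#' @export
readTree <- function(path) {
    if (!file.exists(path)) stop("tree file not found: ", path)
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    .checkBalanced(txt)
    tr <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
        stop("newick parse error in ", path)
    if (anyDuplicated(tr$tip.label))
        stop("duplicate-id error: repeated leaf labels: ",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = ", "))
    tr
}

.checkBalanced <- function(txt) {
    chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
    depth <- 0L
    quoted <- FALSE
    for (i in seq_along(chars)) {
        ch <- chars[i]
        if (ch == "'") quoted <- !quoted
        if (quoted) next
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop("newick parse error: unmatched ')' at character ", i)
        }
    }
    if (depth != 0L)
        stop("newick parse error: ", depth,
             " unclosed '(' at end of input (character ", length(chars), ")")
    invisible(TRUE)
}

#' Root a tree on an outgroup
#'
#' Roots the tree on the edge subtending the given outgroup leaf (or leaf
#' set).  A multi-leaf outgroup must form one side of a split of the
#' unrooted tree; otherwise no rooting exists and an error is raised.
#'
#' @param tree a \code{phylo}.
#' @param outgroup a leaf label or character vector of leaf labels.
#' @return a rooted \code{phylo}.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
    stopifnot(inherits(tree, "phylo"))
    missing <- setdiff(outgroup, tree$tip.label)
    if (length(missing))
        stop("missing-label error: outgroup leaves not in tree: ",
             paste(missing, collapse = ", "))
    if (length(outgroup) >= length(tree$tip.label))
        stop("outgroup cannot contain every leaf")
    tryCatch(
        ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
        error = function(e)
            stop("non-cluster error: outgroup set {",
                 paste(outgroup, collapse = ", "),
                 "} is not a cluster under any rooting", call. = FALSE))
}

#' Diagnose monophyly, paraphyly or polyphyly of a leaf group
#'
#' On a rooted tree, a group is monophyletic when the leaves descending
#' from its most recent common ancestor (MRCA) are exactly the group.
#' Otherwise the extra leaves under the MRCA are the \emph{intruders}:
#' if they form exactly one clade of the rooted tree the group is
#' paraphyletic, if they form more than one it is polyphyletic.
#' Polytomies are allowed; a group whose MRCA is a polytomy is
#' monophyletic only if the leaf-set equality holds.
#'
#' @param tree a rooted \code{phylo}.
#' @param group non-empty character vector of leaf labels.
#' @return list with \code{status} (\code{"monophyletic"},
#'   \code{"paraphyletic"} or \code{"polyphyletic"}) and
#'   \code{intruders} (character vector, empty when monophyletic).
#' @export
assessMonophyly <- function(tree, group) {
    stopifnot(inherits(tree, "phylo"))
    if (!ape::is.rooted(tree)) stop("tree must be rooted")
    if (!length(group)) stop("group must be non-empty")
    unknown <- setdiff(group, tree$tip.label)
    if (length(unknown))
        stop("unknown leaf in group: ", paste(unknown, collapse = ", "))
    under <- .mrcaTips(tree, group)
    intruders <- setdiff(under, group)
    if (!length(intruders))
        return(list(status = "monophyletic", intruders = character()))
    status <- if (setequal(.mrcaTips(tree, intruders), intruders))
        "paraphyletic" else "polyphyletic"
    list(status = status, intruders = sort(intruders))
}

## Leaves descending from the MRCA of a label set (the set itself if of
## size one).
.mrcaTips <- function(tree, labels) {
    if (length(labels) == 1L) return(labels)
    node <- ape::getMRCA(tree, labels)
    tips <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
    tree$tip.label[tips]
}

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard Saitou-Nei agglomerative neighbor joining (via
#' \code{\link[ape]{nj}}) as a self-contained fallback when no externally
#' inferred tree is supplied.  Negative branch lengths are clamped to
#' zero with a warning.  Every pairwise distance must be defined; heavy
#' missing data can leave pairs with no comparable site, in which case
#' the matrix must be recomputed (e.g. after dropping those specimens)
#' before a tree can be built.
#'
#' @param dm a \linkS4class{PDistanceMatrix}.
#' @return an unrooted \code{phylo}.
#' @export
neighborJoining <- function(dm) {
    stopifnot(is(dm, "PDistanceMatrix"))
    d <- dm@d
    if (nrow(d) < 3L) stop("neighbor joining needs at least 3 specimens")
    if (any(is.na(d)))
        stop("undefined distances present; review pairwise deletion or ",
             "drop the affected specimens before tree building")
    tr <- ape::nj(d)
    if (any(tr$edge.length < 0)) {
        warning("negative branch lengths clamped to 0")
        tr$edge.length[tr$edge.length < 0] <- 0
    }
    tr
}
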