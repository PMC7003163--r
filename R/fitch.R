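#' Build a state-annotated rooted binary tree
#'
#' @param tree an \code{ape::phylo} object, a newick string, or a path to a
#'   newick file. Multifurcating or unrooted trees are rejected.
#' @param states named character vector mapping tip labels to state symbols
#'   (\code{NA} or \code{"?"} for unknown). When \code{NULL}, states are
#'   parsed from \code{id=STATE} tip-label suffixes.
#' @return a \linkS4class{StateTree}.
#' @examples
#' st <- stateTree("((A,B),C);", c(A = "W", B = "W", C = "L"))
#' fitchCount(st)$switches
#' @export
stateTree <- function(tree, states = NULL) {
    if (is.character(tree)) {
        tree <- if (length(tree) == 1L && !grepl("[(;]", tree) && file.exists(tree))
            ape::read.tree(tree) else ape::read.tree(text = tree)
        if (is.null(tree)) stop("malformed newick input")
    }
    if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick")
    if (is.null(states)) {
        lab <- tree$tip.label
        if (!all(grepl("=", lab, fixed = TRUE)))
            stop("states not supplied and tip labels are not in id=STATE form")
        parts <- strsplit(lab, "=", fixed = TRUE)
        tree$tip.label <- vapply(parts, `[[`, character(1), 1L)
        states <- setNames(vapply(parts, `[[`, character(1), 2L),
            tree$tip.label)
    }
    states <- setNames(as.character(states), names(states))
    unmatched <- setdiff(names(states), tree$tip.label)
    if (length(unmatched))
        stop(sprintf("state table entry '%s' matches no tip", unmatched[1L]))
    missing <- setdiff(tree$tip.label, names(states))
    if (length(missing))
        stop(sprintf("tip '%s' has no state; use \"?\" for unknown", missing[1L]))
    states <- states[tree$tip.label]
    states[states == "?"] <- NA_character_
    alphabet <- sort(unique(states[!is.na(states)]))
    new("StateTree", tree = tree, tipStates = states, alphabet = alphabet)
}

#' @describeIn stateTree the per-tip state vector (NA = unknown).
#' @param x a \code{StateTree}.
#' @export
tipStates <- function(x) x@tipStates

#' @describeIn stateTree the state alphabet.
#' @export
stateAlphabet <- function(x) x@alphabet

#' @export
setMethod("show", "StateTree", function(object) {
    cat(sprintf("StateTree: %d tips, states {%s}\n",
        length(object@tree$tip.label), paste(object@alphabet, collapse = ", ")))
})

#' Write a state tree as newick with id=STATE tip labels
#'
#' @param x a \linkS4class{StateTree}.
#' @param path optional output file; when \code{NULL} the newick string is
#'   returned.
#' @return the newick string, invisibly when written to a file.
#' @export
writeStateTree <- function(x, path = NULL) {
    stopifnot(is(x, "StateTree"))
    tr <- x@tree
    st <- x@tipStates
    st[is.na(st)] <- "?"
    tr$tip.label <- paste0(tr$tip.label, "=", st[tr$tip.label])
    txt <- ape::write.tree(tr)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Fitch parsimony state sets and minimum switch count
#'
#' Post-order reconstruction on a rooted binary tree: each internal node is
#' assigned the intersection of its two children's state sets when that
#' intersection is nonempty, and their union otherwise. The number of union
#' events equals the minimum number of state switches required by the tree.
#' Unknown tips carry the full alphabet.
#'
#' @param x a \linkS4class{StateTree}.
#' @return list with \code{switches} (the union count) and \code{nodeStates}
#'   (list of state sets indexed as in \code{ape}: tips first in tip order,
#'   then internal nodes; tip entries named by label).
#' @examples
#' st <- stateTree("((Xiphosura,((Eurypterida,Scorpiones),Tetrapulmonata)),Outgroup);",
#'     c(Xiphosura = "W", Eurypterida = "W", Scorpiones = "L",
#'       Tetrapulmonata = "L", Outgroup = "L"))
#' fitchCount(st)$switches   # 2
#' @export
fitchCount <- function(x) {
    stopifnot(is(x, "StateTree"))
    tr <- x@tree
    nTip <- length(tr$tip.label)
    nNode <- tr$Nnode
    sets <- vector("list", nTip + nNode)
    for (i in seq_len(nTip)) {
        s <- x@tipStates[[tr$tip.label[i]]]
        sets[[i]] <- if (is.na(s)) x@alphabet else s
    }
    unions <- 0L
    kidsOf <- split(tr$edge[, 2L], tr$edge[, 1L])
    visit <- function(node) {
        if (node <= nTip) return(sets[[node]])
        kids <- kidsOf[[as.character(node)]]
        s1 <- visit(kids[1L]); s2 <- visit(kids[2L])
        inter <- intersect(s1, s2)
        if (length(inter)) {
            sets[[node]] <<- inter
        } else {
            sets[[node]] <<- sort(union(s1, s2))
            unions <<- unions + 1L
        }
        sets[[node]]
    }
    visit(nTip + 1L)   # root
    names(sets)[seq_len(nTip)] <- tr$tip.label
    names(sets)[(nTip + 1L):(nTip + nNode)] <-
        paste0("node", (nTip + 1L):(nTip + nNode))
    list(switches = unions, nodeStates = sets)
}
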