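## Independent brute-force oracles and small random-data generators used
## by the property-style tests.  These deliberately share no code with
## the package internals: distances are recounted site by site, graph
## components come from breadth-first search, and clades are enumerated
## by explicit traversal of the edge table.

IUPAC_POOL <- c("A", "C", "G", "T", "N", "-", "?", "R", "Y", "W")

randomAlignment <- function(n, L, ambigProb = 0.15,
                            species = NULL) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                nrow = n)
    mask <- matrix(runif(n * L) < ambigProb, nrow = n)
    m[mask] <- sample(c("N", "-", "?", "R", "Y", "W"), sum(mask),
                      replace = TRUE)
    rownames(m) <- sprintf("s%02d", seq_len(n))
    if (is.null(species))
        species <- sprintf("sp%d", rep_len(1:2, n))
    BarcodeAlignment(m, data.frame(specimen_id = rownames(m),
                                   nominal_species = species))
}

## per-pair site-by-site recount of the uncorrected p-distance under
## pairwise deletion
oraclePDistance <- function(x, y) {
    comp <- 0L; mism <- 0L
    for (s in seq_along(x)) {
        a <- x[s]; b <- y[s]
        if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
            comp <- comp + 1L
            if (a != b) mism <- mism + 1L
        }
    }
    list(d = if (comp == 0L) NA_real_ else mism / comp, comp = comp)
}

oracleDistanceMatrix <- function(aln) {
    m <- alignmentMatrix(aln)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    L <- matrix(0L, n, n, dimnames = dimnames(d))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        o <- oraclePDistance(m[i, ], m[j, ])
        d[i, j] <- if (i == j) 0 else o$d
        L[i, j] <- o$comp
    }
    list(d = d, L = L)
}

## connected components of an undirected adjacency matrix by BFS
oracleComponents <- function(adj) {
    n <- nrow(adj)
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (start in seq_len(n)) {
        if (!is.na(comp[start])) next
        k <- k + 1L
        queue <- start
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            if (!is.na(comp[v])) next
            comp[v] <- k
            queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
    }
    comp
}

## all clades (tip-label sets) of a rooted phylo, tips included
enumerateClades <- function(tree) {
    nTip <- length(tree$tip.label)
    kids <- split(tree$edge[, 2L], tree$edge[, 1L])
    tipsUnder <- function(node) {
        if (node <= nTip) return(tree$tip.label[node])
        unlist(lapply(kids[[as.character(node)]], tipsUnder))
    }
    nodes <- c(seq_len(nTip), as.integer(names(kids)))
    lapply(nodes, function(nd) sort(tipsUnder(nd)))
}

## three-way monophyly diagnosis by exhaustive clade enumeration
oracleMonophyly <- function(tree, group) {
    clades <- enumerateClades(tree)
    g <- sort(group)
    isClade <- function(s) any(vapply(clades, identical, logical(1), s))
    if (isClade(g)) return(list(status = "monophyletic",
                                intruders = character()))
    containing <- Filter(function(s) all(g %in% s), clades)
    mrcaTips <- containing[[which.min(lengths(containing))]]
    intr <- sort(setdiff(mrcaTips, g))
    list(status = if (isClade(intr)) "paraphyletic" else "polyphyletic",
         intruders = intr)
}

## build a PDistanceMatrix directly from a symmetric distance matrix
## (for clustering tests that start from distances, not sequences)
dmFromMatrix <- function(d, nSites = 100L) {
    if (is.null(rownames(d)))
        dimnames(d) <- list(letters[seq_len(nrow(d))],
                            letters[seq_len(nrow(d))])
    L <- matrix(as.integer(nSites), nrow(d), ncol(d),
                dimnames = dimnames(d))
    L[is.na(d)] <- 0L
    diag(L) <- as.integer(nSites)
    diag(d) <- 0
    new("PDistanceMatrix", d = d, comparableSites = L,
        deletion = "pairwise")
}

## random symmetric distance matrix with optional undefined pairs
randomDistanceMatrix <- function(n, naProb = 0) {
    d <- matrix(0, n, n)
    v <- runif(n * (n - 1) / 2, 0, 0.12)
    if (naProb > 0) v[runif(length(v)) < naProb] <- NA
    d[upper.tri(d)] <- v
    d <- d + t(d)
    dimnames(d) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
    dmFromMatrix(d)
}

writeTempFasta <- function(seqs, width = 0L) {
    path <- withr::local_tempfile(fileext = ".fasta",
                                  .local_envir = parent.frame())
    lines <- unlist(lapply(names(seqs), function(id) {
        s <- seqs[[id]]
        body <- if (width > 0L)
            substring(s, seq(1, nchar(s), width),
                      pmin(seq(width, nchar(s) + width - 1, width),
                           nchar(s)))
        else s
        c(paste0(">", id), body)
    }))
    writeLines(lines, path)
    path
}

writeTempSpecimens <- function(ids, species, ...) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    utils::write.table(
        data.frame(specimen_id = ids, nominal_species = species, ...),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
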