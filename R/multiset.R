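#' Tree multisets
#'
#' A `tree_multiset` holds the unique topologies of a collection of trees
#' together with their multiplicities (how many times each unique topology
#' occurs). It is the universe over which islands, weights and consensus
#' summaries are computed: parsimony searches yield sets (all
#' multiplicities 1) while Bayesian or bootstrap samples usually yield
#' proper multisets.
#'
#' @param trees a list of trees (`phylo`, `multiPhylo`, Newick strings or
#'   `topology` objects). Repeated topologies are merged and counted.
#' @param counts optional positive integer vector, one per input tree, for
#'   inputs that carry a sidecar count column; defaults to 1 each.
#' @return an object of class `tree_multiset` with fields `labels`,
#'   `topologies` (list of [as_topology()] objects, first-occurrence
#'   order), `multiplicity`, `keys` and `total_mass`.
#' @examples
#' ms <- tree_multiset(list("((A,B),(C,D));", "((C,D),(B,A));"))
#' ms$multiplicity  # 2: the two strings are the same unrooted topology
#' @export
tree_multiset <- function(trees, counts = NULL) {
  if (inherits(trees, "phylo") || inherits(trees, "topology") ||
      (is.character(trees) && length(trees) == 1L)) {
    trees <- list(trees)
  }
  if (length(trees) < 1L) stop_ti("need at least one tree")
  if (is.null(counts)) counts <- rep(1L, length(trees))
  if (length(counts) != length(trees) || any(counts < 1)) {
    stop_ti("counts must be positive, one per input tree")
  }
  topos <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    topos[[i]] <- tryCatch(as_topology(trees[[i]]), error = function(e) {
      stop_ti("tree %d: %s", i, conditionMessage(e))
    })
  }
  labels <- topos[[1L]]$labels
  for (i in seq_along(topos)) {
    if (!identical(topos[[i]]$labels, labels)) {
      stop_ti("tree %d has a different leaf set from tree 1", i)
    }
  }
  keys <- vapply(topos, function(t) t$key, "")
  first <- !duplicated(keys)
  ukeys <- keys[first]
  mult <- vapply(ukeys, function(k) sum(counts[keys == k]), numeric(1),
                 USE.NAMES = FALSE)
  structure(
    list(labels = labels,
         topologies = topos[first],
         multiplicity = as.integer(mult),
         keys = ukeys,
         total_mass = as.integer(sum(counts))),
    class = "tree_multiset")
}

#' @export
print.tree_multiset <- function(x, ...) {
  cat(sprintf("<tree_multiset> %d unique topologies, total mass %d, %d leaves\n",
              length(x$keys), x$total_mass, length(x$labels)))
  invisible(x)
}

#' @export
length.tree_multiset <- function(x) length(x$keys)

# restrict a multiset to the given keys (multiplicities retained)
subset_multiset <- function(trees, keys) {
  idx <- match(keys, trees$keys)
  if (anyNA(idx)) stop_ti("unknown topology key in subset")
  structure(
    list(labels = trees$labels,
         topologies = trees$topologies[idx],
         multiplicity = trees$multiplicity[idx],
         keys = trees$keys[idx],
         total_mass = as.integer(sum(trees$multiplicity[idx]))),
    class = "tree_multiset")
}

#' Read trees into a multiset
#'
#' Reads a Newick list (one tree per line) or a Nexus TREES block
#' (translate tables are resolved to labels) and collapses the trees to
#' unique unrooted topologies with multiplicities. Branch lengths and
#' rooting are parsed and discarded for identity.
#'
#' @param source path to a tree file; ignored when `text` is given.
#' @param format `"newick"` or `"nexus"`.
#' @param text optional character scalar holding the file content directly.
#' @param counts optional per-tree multiplicities (sidecar counts).
#' @return a [tree_multiset()].
#' @export
read_trees <- function(source, format = c("newick", "nexus"), text = NULL,
                       counts = NULL) {
  format <- match.arg(format)
  if (format == "newick") {
    phy <- if (is.null(text)) ape::read.tree(source) else ape::read.tree(text = text)
  } else {
    if (!is.null(text)) {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf))
      writeLines(text, tf)
      source <- tf
    }
    phy <- ape::read.nexus(source)
  }
  if (is.null(phy)) stop_ti("no parsable tree found in input")
  if (inherits(phy, "phylo")) phy <- list(phy)
  tree_multiset(phy, counts = counts)
}

#' Write a tree multiset
#'
#' Writes one Newick line per unique topology, each repeated according to
#' its multiplicity unless `collapse = TRUE`, or a Nexus TREES block with a
#' translate table. When per-topology weights are supplied (see
#' [island_weights()]), Nexus output places a comment of the exact form
#' `[&W p/q]` between the `=` and the tree string, the convention used by
#' PAUP* tree weighting, with the weight written as a literal fraction.
#'
#' @param trees a [tree_multiset()].
#' @param file output path or `""` for stdout.
#' @param format `"newick"` or `"nexus"`.
#' @param weights optional `tree_weights` data frame (columns `key`, `num`,
#'   `den`) covering every topology; only written in Nexus format.
#' @param collapse if `TRUE`, write each unique topology once regardless of
#'   multiplicity.
#' @return invisibly, the character vector of lines written.
#' @export
write_trees <- function(trees, file = "", format = c("newick", "nexus"),
                        weights = NULL, collapse = FALSE) {
  format <- match.arg(format)
  if (!is.null(weights)) {
    miss <- setdiff(trees$keys, weights$key)
    if (length(miss)) stop_ti("weights missing for %d topologies", length(miss))
    extra <- setdiff(weights$key, trees$keys)
    if (length(extra)) stop_ti("weights given for unknown topology key")
  }
  reps <- if (collapse) rep(1L, length(trees$keys)) else trees$multiplicity
  newicks <- vapply(trees$topologies, function(t) {
    blocks_to_newick(t$labels, t$blocks)
  }, "")
  if (format == "newick") {
    out <- rep(newicks, reps)
  } else {
    labs <- trees$labels
    trans <- paste0("\t\t", seq_along(labs), " ", labs,
                    c(rep(",", length(labs) - 1L), ";"))
    num_newicks <- newicks
    for (i in seq_along(labs)) {
      # labels are always flanked by Newick delimiters, so whole-token
      # replacement is safe; escape any regex metacharacters in the label
      esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", labs[i])
      num_newicks <- gsub(paste0("([(,])", esc, "([),:])"),
                          paste0("\\1", i, "\\2"), num_newicks)
    }
    wtag <- rep("", length(newicks))
    if (!is.null(weights)) {
      wi <- match(trees$keys, weights$key)
      # weights are written as the literal fraction m_t/n_i, unreduced
      wtag <- paste0("[&W ", weights$num[wi], "/", weights$den[wi], "] ")
    }
    body <- character(0)
    cnt <- 0L
    for (i in seq_along(newicks)) {
      for (r in seq_len(reps[i])) {
        cnt <- cnt + 1L
        body <- c(body, paste0("\ttree tree_", cnt, " = ", wtag[i],
                               num_newicks[i]))
      }
    }
    out <- c("#NEXUS", "", "BEGIN TREES;", "\tTRANSLATE", trans, body, "END;")
  }
  if (!identical(file, "")) writeLines(out, file) else cat(out, sep = "\n")
  invisible(out)
}
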