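#' Binary Y-SNP marker phylogeny
#'
#' A `marker_tree` encodes the rooted phylogeny of the binary markers of a
#' Y-SNP genotyping panel.  Each tree node is one assayed marker position;
#' the virtual node `ROOT` (every marker ancestral) is implicit.  Recurrent
#' markers -- sites that have mutated more than once in the Y phylogeny,
#' such as SRY10831 (`.1` on the deep branch uniting haplogroups B through
#' T, `.2` the back-mutation on the R1a branch) and P37 (`.1` in haplogroup
#' C, `.2` in I2a1) -- are represented as one node per phylogenetic
#' position, named with the conventional `.1`/`.2` suffixes.
#'
#' @param path Path to a delimited text file with columns `marker`,
#'   `parent` and `major` (single-letter major haplogroup used in call
#'   labels).  `parent` must be `ROOT` for markers hanging directly off the
#'   root.
#' @return An object of class `marker_tree`: a list with elements `marker`,
#'   `parent`, `major` (parallel character vectors), `depth` (integer,
#'   1 for children of ROOT) and `children` (named list).
#' @examples
#' tree <- read_marker_tree(ygeo_tree_file())
#' n_markers(tree)
#' @seealso [assign_haplogroup()], [enumerate_haplogroups()]
#' @export
read_marker_tree <- function(path) {
  df <- read_delim_auto(path)
  need <- c("marker", "parent", "major")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("marker tree file lacks column(s): ", paste(miss, collapse = ", "))
  marker_tree(df$marker, df$parent, df$major)
}

#' Construct a marker tree from vectors
#'
#' @param marker character vector of marker (node) names.
#' @param parent parent marker name for each node, `"ROOT"` for top-level
#'   markers.
#' @param major single-letter (or short) major-haplogroup label per node.
#' @return A `marker_tree` object.
#' @export
marker_tree <- function(marker, parent, major) {
  marker <- as.character(marker)
  parent <- as.character(parent)
  major <- as.character(major)
  if (anyDuplicated(marker))
    stop("duplicated marker name(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if ("ROOT" %in% marker) stop("'ROOT' is reserved for the virtual root")
  unknown <- setdiff(parent, c("ROOT", marker))
  if (length(unknown) > 0)
    stop("parent(s) not in tree: ", paste(unknown, collapse = ", "))
  # depth by iterated resolution; cycles leave nodes unresolved
  depth <- rep(NA_integer_, length(marker))
  names(depth) <- marker
  depth[parent == "ROOT"] <- 1L
  repeat {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    resolved <- !is.na(depth[parent[todo]])
    if (!any(resolved))
      stop("marker tree contains a cycle involving: ",
           paste(marker[todo], collapse = ", "))
    idx <- todo[resolved]
    depth[idx] <- depth[parent[idx]] + 1L
  }
  children <- split(marker, factor(parent, levels = c("ROOT", marker)))
  t <- list(marker = marker, parent = stats::setNames(parent, marker),
            major = stats::setNames(major, marker),
            depth = depth, children = children)
  class(t) <- "marker_tree"
  t
}

#' @export
print.marker_tree <- function(x, ...) {
  cat("Y-SNP marker tree:", length(x$marker), "marker positions,",
      n_haplogroups(x), "distinguishable haplo/paragroups\n")
  invisible(x)
}

#' Number of marker positions in a tree
#' @param tree a `marker_tree`.
#' @return integer count of marker positions (tree nodes).
#' @export
n_markers <- function(tree) length(tree$marker)

#' Path to the packaged canonical 27-marker Y-SNP tree
#'
#' The shipped tree covers the 27 binary markers of the SNPE/Sanger panel
#' (M9, M17, M45, M78, M89, M96, M170, M173, M201, M223, M253, M269, M304,
#' M343, P15, P37, SRY10831, U106/S21, U152/S28, L11/S127, L23/S141, M20,
#' M70, M242, M412/S167, M529/S145, S116) at 29 tree positions (SRY10831
#' and P37 are recurrent and occupy two positions each), yielding 30
#' theoretically distinguishable haplo/paragroups.
#' @return file path of the packaged tree table.
#' @export
ygeo_tree_file <- function() {
  system.file("extdata", "ysnp_tree.tsv", package = "ygeo", mustWork = TRUE)
}

#' Load the packaged canonical marker tree
#' @return a `marker_tree`.
#' @export
ygeo_tree <- function() read_marker_tree(ygeo_tree_file())

path_to_root <- function(tree, node) {
  # ordered ROOT -> node, excluding ROOT
  p <- character(0)
  cur <- node
  while (cur != "ROOT") {
    p <- c(cur, p)
    cur <- tree$parent[[cur]]
  }
  p
}

#' Assign a haplogroup label to a binary SNP genotype
#'
#' The call is the deepest marker whose full ancestor path is supported:
#' every marker on the path is either typed derived or missing, and
#' missing markers are tolerated only because a strictly deeper typed
#' derived marker confirms the path.  A star (paragroup) flag is appended
#' when the terminal marker has at least one typed child and all typed
#' children are ancestral.  A profile that is ancestral at every typed
#' marker receives the ROOT paragroup call (`Y*`).
#'
#' @param genotype named character vector of per-marker states, values in
#'   `c("derived", "ancestral", "missing")` (abbreviations `"D"`, `"A"`
#'   and `""`/`NA` are accepted).  Markers absent from the vector are
#'   treated as untyped (missing).  Names must be tree markers.
#' @param tree a [marker_tree()].
#' @return An object of class `haplogroup_call`: list with `label`,
#'   `terminal` (marker name or `"ROOT"`), `path` (ordered markers
#'   ROOT to terminal), `star` (logical).
#' @details A profile typed derived at a marker whose typed ancestor is
#'   ancestral, or derived at two markers on different branches, is
#'   phylogenetically inconsistent and raises an error naming the
#'   conflicting pair.
#' @examples
#' tree <- ygeo_tree()
#' g <- canonical_profile(tree, "U152/S28")
#' assign_haplogroup(g, tree)$label  # "R-U152/S28"
#' @export
assign_haplogroup <- function(genotype, tree) {
  st <- normalize_states(genotype, tree)
  der <- names(st)[st == "derived"]
  if (length(der) == 0) {
    call <- list(label = "Y*", terminal = "ROOT", path = character(0),
                 star = TRUE)
    class(call) <- "haplogroup_call"
    return(call)
  }
  # consistency: no typed-ancestral marker above a derived marker
  for (m in der) {
    anc <- path_to_root(tree, m)
    anc <- anc[-length(anc)]
    bad <- anc[!is.na(st[anc]) & st[anc] == "ancestral"]
    if (length(bad) > 0)
      stop("inconsistent SNP profile: derived '", m,
           "' under ancestral typed marker '", bad[1], "'")
  }
  term <- der[which.max(tree$depth[der])]
  path <- path_to_root(tree, term)
  # all derived markers must lie on the terminal's root path
  off <- setdiff(der, path)
  if (length(off) > 0)
    stop("inconsistent SNP profile: derived markers '", off[1], "' and '",
         term, "' lie on different branches")
  kids <- tree$children[[term]]
  typed_kids <- if (is.null(kids)) character(0) else
    kids[!is.na(st[kids]) & st[kids] != "missing"]
  star <- length(typed_kids) > 0 && all(st[typed_kids] == "ancestral")
  label <- paste0(tree$major[[term]], "-", term, if (star) "*" else "")
  call <- list(label = label, terminal = term, path = path, star = star)
  class(call) <- "haplogroup_call"
  call
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(x$label, "\n")
  invisible(x)
}

normalize_states <- function(genotype, tree) {
  if (is.null(names(genotype)) && length(genotype) > 0)
    stop("genotype must be a named vector of marker states")
  extra <- setdiff(names(genotype), tree$marker)
  if (length(extra) > 0)
    stop("genotype contains marker(s) not in tree: ",
         paste(extra, collapse = ", "))
  st <- rep(NA_character_, length(tree$marker))
  names(st) <- tree$marker
  v <- as.character(genotype)
  v[is.na(v) | v == ""] <- "missing"
  v <- c(derived = "derived", d = "derived", ancestral = "ancestral",
         a = "ancestral", missing = "missing")[tolower(v)]
  if (anyNA(v))
    stop("unrecognized SNP state(s); use derived/ancestral/missing (D/A/'')")
  st[names(genotype)] <- v
  st[is.na(st)] <- "missing"
  st
}

#' Canonical fully typed profile for a tree outcome
#'
#' Returns the genotype that is derived at the named marker and all its
#' ancestors and ancestral at every other marker; `"ROOT"` gives the
#' all-ancestral profile.
#'
#' @param tree a `marker_tree`.
#' @param node a marker name or `"ROOT"`.
#' @return named character vector of states over all tree markers.
#' @export
canonical_profile <- function(tree, node) {
  st <- stats::setNames(rep("ancestral", length(tree$marker)), tree$marker)
  if (!identical(node, "ROOT")) {
    if (!node %in% tree$marker) stop("unknown marker: ", node)
    st[path_to_root(tree, node)] <- "derived"
  }
  st
}

#' Enumerate all theoretically distinguishable haplo/paragroups
#'
#' One label per distinguishable outcome of fully typing the panel: each
#' terminal clade, each internal star paragroup, and the ROOT paragroup.
#'
#' @param tree a `marker_tree`.
#' @return character vector of labels (ROOT paragroup last); the count is
#'   `length()` of the result.
#' @examples
#' length(enumerate_haplogroups(ygeo_tree()))  # 30
#' @export
enumerate_haplogroups <- function(tree) {
  labs <- vapply(tree$marker, function(m) {
    assign_haplogroup(canonical_profile(tree, m), tree)$label
  }, character(1))
  c(unname(labs), "Y*")
}

#' Count of distinguishable haplo/paragroups
#' @param tree a `marker_tree`.
#' @return integer.
#' @export
n_haplogroups <- function(tree) length(enumerate_haplogroups(tree))
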