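# -------------------------------------------------------------------------
# Newick / extended Newick (eNewick) I/O.
#
# Plain trees go through ape. Networks use the eNewick dialect in which
# each reticulation node appears twice under the label #H<k>: once with
# its child subtree (below its "vertical" parent) and once as a bare
# reference leaf (below the donor; this occurrence marks the horizontal
# transfer arc). Branch annotations follow the three-colon convention
#   label:length:support:gamma
# with the support field left empty; gamma is the inheritance probability
# of the corresponding incoming edge. The writer emits a canonical form
# (children sorted, reticulations renumbered deterministically), so
# write(read(write(x))) == write(x).
# -------------------------------------------------------------------------

fmt_num <- function(x, digits = 10) sprintf("%.*g", digits, x)

#' Serialize a phylogenetic network as extended Newick
#'
#' @param net A `phylo_network` (a plain tree serializes as ordinary
#'   Newick).
#' @param file Optional path; when `NULL` the string is returned.
#' @param digits Significant digits for branch lengths and gamma values.
#' @return The eNewick string (invisibly when written to a file).
#' @export
write_network <- function(net, file = NULL, digits = 10) {
  net <- as_phylo_network(net)
  ret <- reticulation_nodes(net)
  kids <- split(seq_along(net$parent), net$parent)
  # deterministic reticulation labels: rank by descendant-taxa key
  desc_key <- function(v) {
    out <- kids[[v]]
    if (is.null(out)) return(v)
    paste(sort(unlist(lapply(net$child[out], desc_key))), collapse = "|")
  }
  hlab <- stats::setNames(sprintf("#H%d", rank(vapply(ret, desc_key, ""),
                                               ties.method = "first")), ret)
  # pick the "subtree" incoming edge per reticulation node: the
  # non-transfer edge, falling back to the first by edge id
  subtree_edge <- vapply(ret, function(v) {
    i <- which(net$child == v)
    j <- i[!net$transfer[i]]
    if (length(j) == 1L) j else i[order(network_edge_ids(net)[i])][1]
  }, 0L)
  names(subtree_edge) <- ret
  meta <- function(e) {
    g <- net$gamma[e]
    if (is.na(g)) paste0(":", fmt_num(net$length[e], digits))
    else paste0(":", fmt_num(net$length[e], digits), "::", fmt_num(g, digits))
  }
  render_edge <- function(e) {
    v <- net$child[e]
    if (v %in% ret) {
      if (e == subtree_edge[[v]]) {
        paste0(render_node(v), hlab[[v]], meta(e))
      } else {
        paste0(hlab[[v]], meta(e))
      }
    } else {
      paste0(render_node(v), meta(e))
    }
  }
  render_node <- function(v) {
    out <- kids[[v]]
    if (is.null(out)) return(v)
    subs <- sort(vapply(out, render_edge, ""))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  s <- paste0(render_node(net$root), ";")
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

#' Parse a tree or network from (extended) Newick
#'
#' Reads a Newick string or file. Text containing `#H` reticulation
#' labels is parsed as an extended-Newick network (the reference
#' occurrence of each `#H` node is taken as the horizontal transfer arc,
#' and gamma annotations in `:length::gamma` position are read from both
#' incoming edges, with a missing one filled by complementation);
#' anything else is parsed with [ape::read.tree()].
#'
#' @param x A file path or a Newick/eNewick string.
#' @return An [ape::phylo] tree or a `phylo_network`.
#' @export
read_phylogeny <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[();]", x) && file.exists(x)) {
    paste(readLines(x), collapse = "")
  } else paste(x, collapse = "")
  txt <- gsub("\\s", "", txt)
  if (!grepl("#", txt, fixed = TRUE)) {
    return(ape::read.tree(text = txt))
  }
  parse_enewick(txt)
}

parse_enewick <- function(txt) {
  pos <- 1L
  n <- nchar(txt)
  peek <- function() if (pos <= n) substr(txt, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop(sprintf("eNewick parse error at position %d: %s",
                                     pos, msg), call. = FALSE)
  read_name <- function() {
    start <- pos
    while (pos <= n && !substr(txt, pos, pos) %in% c("(", ")", ",", ":", ";")) {
      advance()
    }
    substr(txt, start, pos - 1L)
  }
  read_number <- function() {
    start <- pos
    while (pos <= n && grepl("[-0-9.eE+]", substr(txt, pos, pos))) advance()
    if (pos == start) return(NA_real_)
    as.numeric(substr(txt, start, pos - 1L))
  }
  counter <- 0L
  edges <- list()
  # returns the node id of the parsed subtree and attaches edge metadata
  parse_subtree <- function() {
    children <- list()
    if (peek() == "(") {
      advance()
      repeat {
        children[[length(children) + 1L]] <- parse_subtree()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    name <- read_name()
    len <- NA_real_; gam <- NA_real_
    if (peek() == ":") {
      advance(); len <- read_number()
      if (peek() == ":") {
        advance(); read_number()  # support field, ignored
        if (peek() == ":") { advance(); gam <- read_number() }
      }
    }
    id <- if (nzchar(name)) name else {
      counter <<- counter + 1L
      sprintf(".anon%d", counter)
    }
    for (ch in children) {
      edges[[length(edges) + 1L]] <<- list(parent = id, child = ch$id,
                                           length = ch$len, gamma = ch$gam,
                                           leafref = ch$leafref)
    }
    list(id = id, len = len, gam = gam,
         leafref = !length(children) && grepl("^#", name))
  }
  root <- parse_subtree()
  if (peek() != ";") fail("expected ';'")
  parent <- vapply(edges, `[[`, "", "parent")
  child <- vapply(edges, `[[`, "", "child")
  len <- vapply(edges, `[[`, 0, "length")
  gam <- vapply(edges, `[[`, 0, "gamma")
  leafref <- vapply(edges, `[[`, TRUE, "leafref")
  if (anyNA(len)) fail("every edge needs a branch length")
  # rename anonymous internals deterministically
  ids <- unique(c(root$id, parent, child))
  internal <- setdiff(unique(parent), child)  # just the root if anonymous
  relab <- stats::setNames(ids, ids)
  anon <- grep("^\\.anon", ids, value = TRUE)
  relab[anon] <- sprintf("n%d", seq_along(anon))
  parent <- relab[parent]; child <- relab[child]; rootid <- relab[[root$id]]
  # gamma completion per reticulation node
  net <- new_phylo_network(parent, child, len, gam, leafref, rootid)
  for (v in reticulation_nodes(net)) {
    i <- which(net$child == v)
    g <- net$gamma[i]
    if (all(is.na(g))) {
      stop("reticulation node '", v,
           "' carries no inheritance probability", call. = FALSE)
    }
    if (anyNA(g)) net$gamma[i[is.na(g)]] <- 1 - g[!is.na(g)]
  }
  bad <- validate_network(net)
  if (length(bad)) {
    stop("parsed network is invalid:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  net
}
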