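# S3 methods and network construction for the fitted "reticulogram" object.

#' Build the hybridization network from fitted formulas
#'
#' One node per distinct genotype entry (taxon, nuclear genotype string,
#' chloroplast haplotype); directed edges run from parental genotype nodes to
#' hybrid nodes, typed `maternal` or `paternal`. Ambiguity sets expand to
#' parallel edges flagged `ambiguous`; parental lineages with no sampled
#' parental taxon become dashed `unknown` placeholder nodes. Hybrid nodes
#' lacking either a maternal or a paternal in-edge carry `incomplete = TRUE`.
#'
#' @param fit a `"reticulogram"` object (called internally by
#'   [infer_reticulation()]).
#' @return list with `nodes`, `edges` data frames and `graph` (an
#'   `igraph` object).
#' @export
build_reticulogram <- function(fit) {
  f <- fit$formulas
  samples <- fit$samples
  meta_of <- function(col) {
    if (col %in% names(samples)) {
      stats::setNames(samples[[col]], samples$sample_id)
    } else {
      stats::setNames(rep(NA_character_, nrow(samples)), samples$sample_id)
    }
  }
  ploidy_of <- stats::setNames(samples$ploidy, samples$sample_id)
  mode_of <- meta_of("mode"); habitat_of <- meta_of("habitat")
  elev_of <- meta_of("elevation_class")

  node_id <- function(taxon, genotype, cp) {
    paste(taxon, ifelse(is.na(genotype), "-", genotype),
          ifelse(is.na(cp), "-", cp), sep = " | ")
  }
  f$node <- node_id(f$taxon, f$genotype, f$cp_haplotype)
  nodes <- f[!duplicated(f$node),
             c("node", "taxon", "genotype", "cp_haplotype", "status")]
  first_sid <- f$sample_id[!duplicated(f$node)]
  nodes$ploidy <- unname(ploidy_of[first_sid])
  nodes$mode <- unname(mode_of[first_sid])
  nodes$habitat <- unname(habitat_of[first_sid])
  nodes$elevation_class <- unname(elev_of[first_sid])
  nodes$placeholder <- FALSE

  # parental genotype nodes per taxon (possibly several), and the alleles
  # each carries, so an edge starts at the parental node owning the allele
  parental <- f[f$status == "parental", ]
  parental_nodes_of <- split(parental$node, parental$taxon)
  node_alleles <- stats::setNames(vector("list", nrow(parental)),
                                  parental$node)
  for (i in seq_len(nrow(parental))) {
    g <- fit$genotypes[fit$genotypes$sample_id == parental$sample_id[i] &
                         fit$genotypes$locus_id == fit$primary_locus, ]
    node_alleles[[parental$node[i]]] <-
      if (nrow(g) == 1L) unique(g$alleles[[1L]]) else character(0L)
  }

  edges <- list()
  placeholders <- character(0L)
  add_edge <- function(from, to, type, ambiguous) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, ambiguous = ambiguous,
      stringsAsFactors = FALSE)
  }
  parent_nodes_for <- function(taxon, alleles_hint) {
    pn <- parental_nodes_of[[sub("\\?$", "", taxon)]]
    if (is.null(pn)) return(character(0L))
    if (length(pn) > 1L && length(alleles_hint) > 0L) {
      own <- pn[vapply(pn, function(nd)
        any(alleles_hint %in% node_alleles[[nd]]), logical(1L))]
      if (length(own) > 0L) return(own)
    }
    pn
  }
  hyb <- f[f$status %in% c("hybrid", "unresolved"), ]
  for (i in seq_len(nrow(hyb))) {
    if (duplicated(hyb$node)[i]) next
    to <- hyb$node[i]
    m_taxa <- strsplit(hyb$maternal[i], ",", fixed = TRUE)[[1L]]
    p_taxa <- strsplit(hyb$paternal[i], ",", fixed = TRUE)[[1L]]
    m_alleles <- strsplit(hyb$maternal_alleles[i], ",", fixed = TRUE)[[1L]]
    for (mt in m_taxa) {
      if (mt == "unknown") {
        ph <- "unknown maternal lineage"
        placeholders <- union(placeholders, ph)
        add_edge(ph, to, "maternal", TRUE)
      } else {
        amb <- isTRUE(hyb$ambiguous[i]) || length(m_taxa) > 1L ||
          grepl("\\?$", mt)
        for (pn in parent_nodes_for(mt, m_alleles)) {
          add_edge(pn, to, "maternal", amb)
        }
      }
    }
    for (pt in p_taxa) {
      if (pt == "unknown") {
        ph <- "unknown paternal lineage"
        placeholders <- union(placeholders, ph)
        add_edge(ph, to, "paternal", TRUE)
      } else {
        for (pn in parent_nodes_for(pt, character(0L))) {
          add_edge(pn, to, "paternal", length(p_taxa) > 1L || grepl("\\?$", pt))
        }
      }
    }
  }
  edges <- if (length(edges) > 0L) unique(do.call(rbind, edges)) else
    data.frame(from = character(), to = character(), type = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  if (length(placeholders) > 0L) {
    ph_nodes <- data.frame(node = placeholders, taxon = "unknown",
                           genotype = NA_character_,
                           cp_haplotype = NA_character_, status = "parental",
                           ploidy = NA_integer_, mode = NA_character_,
                           habitat = NA_character_,
                           elevation_class = NA_character_,
                           placeholder = TRUE, stringsAsFactors = FALSE)
    nodes <- rbind(nodes, ph_nodes)
  }
  rownames(nodes) <- NULL
  in_types <- lapply(nodes$node, function(nd) unique(edges$type[edges$to == nd]))
  nodes$incomplete <- nodes$status != "parental" &
    !(vapply(in_types, function(tt) all(c("maternal", "paternal") %in% tt),
             logical(1L)))

  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  list(nodes = nodes, edges = edges, graph = g)
}

#' Summarize a fitted reticulogram
#'
#' Reports the headline bookkeeping: total genotype entries, parental and
#' hybrid counts, the number of putative parental taxa (over confidently
#' determined names, i.e. excluding "aff."/"cf." qualified determinations;
#' the unrestricted count is also reported), and per-parental-taxon hybrid
#' counts. Per-lineage counts are over *distinct hybrid nuclear genotype
#' strings* at the primary locus, with parent-set membership decided by exact
#' allele match to a homozygous parental taxon, reported under the maternal,
#' paternal and either-role definitions.
#'
#' @param object a `"reticulogram"` object.
#' @param ... unused.
#' @return an object of class `"summary.reticulogram"`: a list with
#'   `total_genotypes`, `parental_genotypes`, `hybrid_genotypes`,
#'   `parental_taxa`, `parental_taxa_all`, `parental_taxon_names` and
#'   `lineage_counts` (a `data.frame` with `taxon`, `n_maternal`,
#'   `n_paternal`, `n_either`).
#' @export
summary.reticulogram <- function(object, ...) {
  f <- object$formulas
  total <- nrow(f)
  parental <- sum(f$status == "parental")
  hybrid <- total - parental
  ptaxa_all <- sort(unique(f$taxon[f$status == "parental"]))
  confident <- !grepl("(^| )(aff|cf)\\. ", ptaxa_all)
  ptaxa <- ptaxa_all[confident]

  hyb <- f[f$status != "parental" & !is.na(f$genotype), ]
  strings <- unique(hyb$genotype)
  per_string <- lapply(strings, function(s) {
    rows <- hyb[hyb$genotype == s, ]
    list(
      either = unique(unlist(rows$parent_set)),
      maternal = intersect(
        unique(unlist(strsplit(rows$maternal, ",", fixed = TRUE))),
        unique(unlist(rows$parent_set))),
      paternal = intersect(
        sub("\\?$", "",
            unique(unlist(strsplit(rows$paternal, ",", fixed = TRUE)))),
        unique(unlist(rows$parent_set))))
  })
  all_parents <- sort(unique(unlist(lapply(per_string, `[[`, "either"))))
  lineage_counts <- data.frame(
    taxon = all_parents,
    n_maternal = vapply(all_parents, function(tx)
      sum(vapply(per_string, function(p) tx %in% p$maternal, logical(1L))),
      integer(1L)),
    n_paternal = vapply(all_parents, function(tx)
      sum(vapply(per_string, function(p) tx %in% p$paternal, logical(1L))),
      integer(1L)),
    n_either = vapply(all_parents, function(tx)
      sum(vapply(per_string, function(p) tx %in% p$either, logical(1L))),
      integer(1L)),
    stringsAsFactors = FALSE)
  lineage_counts <- lineage_counts[order(-lineage_counts$n_either,
                                         lineage_counts$taxon), ]
  rownames(lineage_counts) <- NULL

  structure(list(total_genotypes = total,
                 parental_genotypes = parental,
                 hybrid_genotypes = hybrid,
                 parental_taxa = length(ptaxa),
                 parental_taxa_all = length(ptaxa_all),
                 parental_taxon_names = ptaxa,
                 lineage_counts = lineage_counts),
            class = "summary.reticulogram")
}

#' @export
print.summary.reticulogram <- function(x, ...) {
  cat("Reticulate-evolution summary\n")
  cat("  genotype entries:        ", x$total_genotypes, "\n")
  cat("  putative parental:       ", x$parental_genotypes, "\n")
  cat("  of hybrid origin:        ", x$hybrid_genotypes, "\n")
  cat("  putative parental taxa:  ", x$parental_taxa,
      " (", x$parental_taxa_all, " incl. uncertain determinations)\n",
      sep = "")
  cat("  parental lineages (distinct hybrid genotypes, either role):\n")
  top <- utils::head(x$lineage_counts, 10L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-32s %3d (maternal %d, paternal %d)\n", top$taxon[i],
                top$n_either[i], top$n_maternal[i], top$n_paternal[i]))
  }
  invisible(x)
}

#' @export
print.reticulogram <- function(x, ...) {
  cat("<reticulogram> fitted on ", nrow(x$formulas), " genotype entries (",
      x$primary_locus, " + ", x$cp_locus, ")\n", sep = "")
  cat("  nodes: ", nrow(x$network$nodes), ", edges: ",
      nrow(x$network$edges), "\n", sep = "")
  s <- summary(x)
  cat("  parental ", s$parental_genotypes, " / hybrid ",
      s$hybrid_genotypes, " / parental taxa ", s$parental_taxa, "\n",
      sep = "")
  invisible(x)
}

#' Plot a reticulogram
#'
#' Draws the hybridization network: red edges are maternal contributions,
#' blue edges paternal; dashed edges mark ambiguity; circles are diploids,
#' squares triploids, and placeholder (undiscovered) parents are grey.
#'
#' @param x a `"reticulogram"` object.
#' @param ... passed to `igraph::plot.igraph()`.
#' @export
plot.reticulogram <- function(x, ...) {
  g <- x$network$graph
  ec <- ifelse(igraph::E(g)$type == "maternal", "firebrick", "steelblue")
  el <- ifelse(igraph::E(g)$ambiguous, 2L, 1L)
  vs <- ifelse(!is.na(igraph::V(g)$ploidy) & igraph::V(g)$ploidy == 3L,
               "square", "circle")
  vc <- ifelse(igraph::V(g)$placeholder, "grey80",
               ifelse(igraph::V(g)$status == "parental", "palegreen",
                      "lightgoldenrod"))
  igraph::plot.igraph(g, edge.color = ec, edge.lty = el, vertex.shape = vs,
                      vertex.color = vc, vertex.label.cex = 0.6,
                      edge.arrow.size = 0.4, ...)
  invisible(x)
}

#' Export a reticulogram to GML or DOT
#'
#' Writes the network with `type` (maternal/paternal) and `ambiguous` edge
#' attributes and ploidy/mode/habitat node attributes.
#'
#' @param x a `"reticulogram"` object.
#' @param path output file.
#' @param format `"gml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_reticulogram <- function(x, path, format = c("gml", "dot")) {
  format <- match.arg(format)
  g <- x$network$graph
  # igraph's writers are strict about attribute types
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (is.logical(v)) g <- igraph::set_vertex_attr(g, a, value = as.integer(v))
    v <- igraph::vertex_attr(g, a)
    if (is.character(v) || anyNA(v)) {
      v[is.na(v)] <- ""
      g <- igraph::set_vertex_attr(g, a, value = as.character(v))
    }
  }
  for (a in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, a)
    if (is.logical(v)) g <- igraph::set_edge_attr(g, a, value = as.integer(v))
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
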