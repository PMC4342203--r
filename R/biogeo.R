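# Classification and time-binning of speciation-process events from a dated
# tree plus per-node ancestral range assignments: node-based events
# (vicariance, peripheral isolation, within-area speciation) and branch-based
# events (dispersal = area gain, extinction = area loss).

#' Default area alphabet
#'
#' Eight biogeographic regions spanning the African succulent-flora study
#' system, as single-letter codes: Southern African (S), Zambezian (Z),
#' Congolian (C), Ethiopian-Somalian (E), Saharan-Sudanian (N), Arabia (A),
#' Madagascar (M), Eurasia (U).
#'
#' @return named character vector: codes with region names.
#' @export
default_areas <- function() {
  c(S = "Southern_African", Z = "Zambezian", C = "Congolian",
    E = "Ethiopian-Somalian", N = "Saharan-Sudanian", A = "Arabia",
    M = "Madagascar", U = "Eurasia")
}

#' Construct a range assignment
#'
#' A per-node map to area sets, stored as strings of sorted single-letter
#' codes indexed by node number (tips `1..n` first, then internal nodes).
#' `inherited`, when present, records the range at the start of each node's
#' subtending branch (i.e. the node's share of its parent's cladogenetic
#' split); the forward simulator fills it in, reconstructions from real data
#' usually cannot.
#'
#' @param ranges character vector of area-code strings per node.
#' @param areas area alphabet (single-letter codes).
#' @param inherited optional character vector of branch-start ranges
#'   (`NA` for the root).
#' @param tip_labels optional tip labels, for reporting.
#' @return an object of class `"range_assignment"`.
#' @export
range_assignment <- function(ranges, areas = names(default_areas()),
                             inherited = NULL, tip_labels = NULL) {
  ranges <- as.character(ranges)
  bad <- vapply(ranges, function(s)
    !is.na(s) && nzchar(s) && !all(.string_to_range(s) %in% areas), TRUE)
  if (any(bad))
    stop_validation("ranges use areas outside the alphabet: %s",
                    paste(unique(ranges[bad]), collapse = ", "))
  structure(list(ranges = ranges, areas = as.character(areas),
                 inherited = inherited, tip_labels = tip_labels),
            class = "range_assignment")
}

#' @export
print.range_assignment <- function(x, ...) {
  cat(sprintf("Range assignment over %d nodes, areas {%s}%s\n",
              length(x$ranges), paste(x$areas, collapse = ""),
              if (is.null(x$inherited)) ""
              else ", with branch-start ranges"))
  invisible(x)
}

#' Pick the most probable range per node
#'
#' Reduces a table of candidate ranges with relative probabilities to a
#' single range per node: the highest-probability candidate, ties broken by
#' smaller range size then lexicographic order. Candidates below
#' `min_probability` are discarded first.
#'
#' @param prob_table data frame with columns `node` (integer), `range`
#'   (area-code string) and `probability`.
#' @param areas area alphabet.
#' @param min_probability probability floor; candidates below it are ignored.
#' @param n_nodes total number of nodes expected (defaults to `max(node)`).
#' @return a [range_assignment].
#' @export
most_probable_ranges <- function(prob_table, areas = names(default_areas()),
                                 min_probability = 0, n_nodes = NULL) {
  need <- c("node", "range", "probability")
  if (!all(need %in% names(prob_table)))
    stop_validation("prob_table needs columns %s", paste(need, collapse = ", "))
  prob_table <- prob_table[prob_table$probability >= min_probability, ,
                           drop = FALSE]
  if (is.null(n_nodes)) n_nodes <- max(prob_table$node, 0L)
  out <- rep(NA_character_, n_nodes)
  for (v in unique(prob_table$node)) {
    cand <- prob_table[prob_table$node == v, , drop = FALSE]
    cand$range <- vapply(cand$range,
                         function(s) .range_to_string(.string_to_range(s)), "")
    ord <- order(-cand$probability, nchar(cand$range), cand$range)
    out[v] <- cand$range[ord[1L]]
  }
  empty <- setdiff(seq_len(n_nodes), unique(prob_table$node))
  if (length(empty))
    stop_validation("no candidate range for node(s): %s",
                    paste(utils::head(empty, 5), collapse = ", "))
  range_assignment(out, areas = areas)
}

#' Classify a cladogenetic event from parent and child ranges
#'
#' Rules: a single-area parent copied to both children is within-area
#' speciation; disjoint child ranges whose union is the parent range is
#' vicariance; one child keeping the full parent range while the other takes
#' a single area of it is peripheral isolation. Anything else is
#' `"unclassified"` (counted, never dropped). Symmetric in child order.
#'
#' @param parent,child1,child2 area sets, as code strings or character
#'   vectors.
#' @return one of `"within_area"`, `"vicariance"`, `"peripheral_isolation"`,
#'   `"unclassified"`.
#' @export
classify_cladogenetic <- function(parent, child1, child2) {
  P <- if (is.character(parent) && length(parent) == 1L)
    .string_to_range(parent) else as.character(parent)
  C1 <- if (is.character(child1) && length(child1) == 1L)
    .string_to_range(child1) else as.character(child1)
  C2 <- if (is.character(child2) && length(child2) == 1L)
    .string_to_range(child2) else as.character(child2)
  if (!length(P) || !length(C1) || !length(C2)) return("unclassified")
  same <- function(a, b) setequal(a, b)
  if (length(P) == 1L && same(C1, P) && same(C2, P)) return("within_area")
  if (!length(intersect(C1, C2)) && same(union(C1, C2), P))
    return("vicariance")
  per <- function(keep, iso)
    same(keep, P) && length(iso) == 1L && iso %in% P && !same(iso, P)
  if (per(C1, C2) || per(C2, C1)) return("peripheral_isolation")
  "unclassified"
}

# Rule-based branch-start (inherited) range when the simulator truth is not
# available: classified patterns imply their own inheritance; otherwise fall
# back to the parent/child intersection (or the parent range if disjoint).
.fallback_inherited <- function(P, C1, C2) {
  type <- classify_cladogenetic(P, C1, C2)
  if (type %in% c("vicariance", "peripheral_isolation"))
    return(list(type = type, inh = list(C1, C2)))
  if (length(P) == 1L)
    return(list(type = "within_area", inh = list(P, P)))
  inh <- lapply(list(C1, C2), function(C) {
    shared <- intersect(P, C)
    if (length(shared)) shared else P
  })
  list(type = type, inh = inh)
}

#' Infer biogeographic events from node ranges on a dated tree
#'
#' At each internal node the cladogenetic event is classified
#' ([classify_cladogenetic]) and logged at the node age; along each branch
#' the inherited (branch-start) range is compared with the child node's
#' range: every gained area is one dispersal and every lost area one
#' extinction, logged at the branch midpoint by default. When `ranges`
#' carries the simulator's true branch-start ranges these are used directly,
#' making the classification an exact inverse of the forward process;
#' otherwise inheritance is reconstructed from the classification rules.
#'
#' @param tree a dated `phylo`.
#' @param ranges a [range_assignment] covering every node.
#' @param branch_event_time `"midpoint"` (default) or `"random"` placement of
#'   branch events within the branch's age interval.
#' @param seed used only for `branch_event_time = "random"`.
#' @return an `event_log` data frame (`type`, `time`, `node`, `areas`) sorted
#'   by decreasing age, with attribute `root_age`.
#' @export
infer_events <- function(tree, ranges,
                         branch_event_time = c("midpoint", "random"),
                         seed = NULL) {
  check_phylo(tree)
  branch_event_time <- match.arg(branch_event_time)
  if (!inherits(ranges, "range_assignment"))
    stop_validation("ranges must be a range_assignment")
  ntot <- n_tips(tree) + tree$Nnode
  if (length(ranges$ranges) < ntot)
    stop_validation("range assignment covers %d of %d nodes",
                    length(ranges$ranges), ntot)
  unassigned <- which(is.na(ranges$ranges[seq_len(ntot)]) |
                        !nzchar(ranges$ranges[seq_len(ntot)]))
  if (length(unassigned))
    stop_validation("missing range for node(s): %s",
                    paste(utils::head(unassigned, 5), collapse = ", "))
  ages <- node_ages(tree)
  have_truth <- !is.null(ranges$inherited)
  with_seed(seed, {
    log <- list()
    add <- function(type, time, node, area_str) {
      log[[length(log) + 1L]] <<-
        data.frame(type = type, time = time, node = node, areas = area_str)
    }
    po <- ape::reorder.phylo(tree, "postorder")
    internal_order <- rev(unique(po$edge[, 1L]))
    for (v in internal_order) {
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      P <- .string_to_range(ranges$ranges[v])
      kidranges <- lapply(kids, function(ch) .string_to_range(ranges$ranges[ch]))
      if (have_truth) {
        inh <- lapply(kids, function(ch) .string_to_range(ranges$inherited[ch]))
        type <- classify_cladogenetic(P, inh[[1L]],
                                      if (length(inh) > 1L) inh[[2L]] else inh[[1L]])
      } else {
        fb <- .fallback_inherited(P, kidranges[[1L]],
                                  if (length(kidranges) > 1L) kidranges[[2L]]
                                  else kidranges[[1L]])
        type <- fb$type
        inh <- fb$inh
        if (length(kids) > 2L)   # polytomy: extra children inherit the parent range
          for (j in 3:length(kids)) inh[[j]] <- P
      }
      area_str <- switch(type,
        within_area = .range_to_string(P),
        vicariance = paste(.range_to_string(inh[[1L]]),
                           .range_to_string(inh[[2L]]), sep = "|"),
        peripheral_isolation = {
          iso <- inh[[which.min(lengths(inh))]]
          paste(.range_to_string(P), .range_to_string(iso), sep = "|")
        },
        paste(vapply(inh, .range_to_string, ""), collapse = "|"))
      add(type, ages[[v]], v, area_str)
      for (j in seq_along(kids)) {
        ch <- kids[j]
        start <- inh[[j]]
        endr <- kidranges[[j]]
        gains <- setdiff(endr, start)
        losses <- setdiff(start, endr)
        tmid <- function() {
          if (branch_event_time == "midpoint")
            (ages[[v]] + ages[[ch]]) / 2
          else stats::runif(1L, ages[[ch]], ages[[v]])
        }
        for (g in gains) add("dispersal", tmid(), ch, g)
        for (l in losses) add("extinction", tmid(), ch, l)
      }
    }
    log <- do.call(rbind, log)
    log <- log[order(-log$time), , drop = FALSE]
    rownames(log) <- NULL
    structure(log, class = c("event_log", "data.frame"),
              root_age = unname(attr(ages, "depth")))
  })
}

#' Bin an event log through time
#'
#' Counts events per type in bins of width `bin_width` running from the root
#' age down to the present. Bin `[k*w, (k-1)*w)` covers ages
#' `(k-1)*w < t <= k*w`, so an event at age 3.2 with width 1 falls in bin
#' `[4,3)`. Within-area speciation is excluded from the default four-category
#' histogram but remains in the log.
#'
#' @param log an `event_log` (from [infer_events] or the forward simulator).
#' @param bin_width bin width in the tree's time units (> 0).
#' @param types event types to tabulate.
#' @param root_age top of the oldest bin; defaults to the log's `root_age`
#'   attribute.
#' @return matrix of counts, rows = bins labelled `[upper,lower)` (oldest
#'   first), columns = types; attribute `edges` holds the bin edges.
#' @export
bin_events <- function(log, bin_width,
                       types = c("dispersal", "extinction", "vicariance",
                                 "peripheral_isolation"),
                       root_age = attr(log, "root_age")) {
  if (is.null(bin_width) || bin_width <= 0)
    stop_validation("bin_width must be > 0")
  if (is.null(root_age)) root_age <- max(log$time, 0)
  n_bins <- max(1L, as.integer(ceiling(root_age / bin_width - 1e-12)))
  counts <- matrix(0L, n_bins, length(types),
                   dimnames = list(
                     sprintf("[%g,%g)", (n_bins:1) * bin_width,
                             (n_bins:1 - 1) * bin_width),
                     types))
  sub <- log[log$type %in% types, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    k <- max(1L, as.integer(ceiling(sub$time[i] / bin_width - 1e-12)))
    if (k > n_bins) k <- n_bins
    row <- n_bins - k + 1L
    col <- match(sub$type[i], types)
    counts[row, col] <- counts[row, col] + 1L
  }
  structure(counts, edges = (n_bins:0) * bin_width, bin_width = bin_width)
}

#' Read and write range tables
#'
#' Delimited text with columns `node` (node number or tip label), `range`
#' (concatenated single-letter area codes) and optionally `probability`.
#'
#' @param path file path.
#' @param tree optional `phylo` used to resolve tip labels to node numbers.
#' @param areas area alphabet.
#' @param sep field separator.
#' @return `read_range_table()`: a data frame (`node`, `range`,
#'   `probability`); feed it to [most_probable_ranges] or directly to
#'   [range_assignment].
#' @export
read_range_table <- function(path, tree = NULL,
                             areas = names(default_areas()), sep = "\t") {
  if (!file.exists(path)) stop_validation("range file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("node", "range") %in% names(tab)))
    stop_validation("range table needs columns node, range")
  if (!is.null(tree)) {
    lab <- normalise_label(as.character(tab$node))
    hit <- match(lab, tree$tip.label)
    num <- suppressWarnings(as.integer(as.character(tab$node)))
    tab$node <- ifelse(!is.na(hit), hit, num)
    if (anyNA(tab$node))
      stop_validation("unresolvable node identifiers in %s", path)
  } else {
    tab$node <- as.integer(tab$node)
  }
  if (is.null(tab$probability)) tab$probability <- 1
  tab
}

#' @rdname read_range_table
#' @param log an `event_log` or binned-event matrix to write.
#' @export
write_event_log <- function(log, path, sep = "\t") {
  utils::write.table(as.data.frame(log), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
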