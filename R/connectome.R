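#' Construct a connectome object
#'
#' A connectome holds an ordered neuron list, directed chemical edges and
#' undirected electrical (gap-junction) edges. The analysis network is the
#' combined directed binary graph in which each gap junction is treated as a
#' bidirectional connection; synapse-count weights are retained as metadata.
#'
#' @param neurons character vector of neuron names (ordered, unique).
#' @param chem data.frame with columns `pre`, `post`, `weight` (directed
#'   chemical synapses, at most one record per ordered pair).
#' @param gap data.frame with columns `a`, `b`, `weight` (undirected gap
#'   junctions, at most one record per unordered pair).
#' @param neuron_table optional per-neuron annotation data.frame (see
#'   [read_neuron_table()]); row order is matched to `neurons`.
#' @return an object of class `connectome`.
#' @export
connectome <- function(neurons, chem = NULL, gap = NULL, neuron_table = NULL) {
  neurons <- trimws(as.character(neurons))
  if (anyDuplicated(neurons)) stop_data("duplicate neuron names in neuron list")
  empty_chem <- data.frame(pre = character(), post = character(),
                           weight = numeric(), stringsAsFactors = FALSE)
  empty_gap <- data.frame(a = character(), b = character(),
                          weight = numeric(), stringsAsFactors = FALSE)
  chem <- if (is.null(chem) || nrow(chem) == 0) empty_chem else
    data.frame(pre = trimws(as.character(chem$pre)),
               post = trimws(as.character(chem$post)),
               weight = if ("weight" %in% names(chem)) as.numeric(chem$weight) else 1,
               stringsAsFactors = FALSE)
  gap <- if (is.null(gap) || nrow(gap) == 0) empty_gap else
    data.frame(a = trimws(as.character(gap$a)),
               b = trimws(as.character(gap$b)),
               weight = if ("weight" %in% names(gap)) as.numeric(gap$weight) else 1,
               stringsAsFactors = FALSE)

  bad <- setdiff(unique(c(chem$pre, chem$post, gap$a, gap$b)), neurons)
  if (length(bad) > 0)
    stop_data("edge endpoint(s) not in neuron list: %s",
              paste(utils::head(bad, 5), collapse = ", "))
  if (any(chem$pre == chem$post) || any(gap$a == gap$b))
    stop_data("self-edges are not allowed")
  if (anyDuplicated(paste(chem$pre, chem$post)))
    stop_data("duplicate chemical record for an ordered pair")
  # canonical order for gap records
  if (nrow(gap) > 0) {
    swap <- gap$a > gap$b
    tmp <- gap$a[swap]; gap$a[swap] <- gap$b[swap]; gap$b[swap] <- tmp
    if (anyDuplicated(paste(gap$a, gap$b)))
      stop_data("duplicate gap record for an unordered pair")
  }
  if (any(chem$weight < 1) || any(gap$weight < 1))
    stop_data("edge weights must be >= 1")

  structure(list(neurons = neurons, chem = chem, gap = gap,
                 neuron_table = neuron_table),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d neurons, %d chemical records, %d gap records\n",
              length(x$neurons), nrow(x$chem), nrow(x$gap)))
  cat(sprintf("  %d directed connections, %d connected unordered pairs\n",
              nrow(directed_edges(x)), nrow(connected_pairs(x))))
  invisible(x)
}

#' Read a neuron annotation table
#'
#' Expected tab-separated columns: `neuron`, `x_um`, `y_um`,
#' `region` (head/body/tail), `types` (semicolon-separated subset of
#' sensory/motor/interneuron), `neurotransmitter`, `birth_time_min`,
#' `bilateral_partner`, `command_interneuron` (0/1). An optional
#' `mirror_from` column names a contralateral neuron whose coordinates are
#' copied when `x_um`/`y_um` are missing (used for neurons whose positions
#' were not recorded).
#'
#' @param path TSV file path.
#' @return data.frame, one row per neuron.
#' @export
read_neuron_table <- function(path) {
  if (!file.exists(path)) stop_data("neuron table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("neuron", "x_um", "y_um", "region")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop_data("neuron table missing column(s): %s", paste(miss, collapse = ", "))
  tab$neuron <- trimws(tab$neuron)
  if ("mirror_from" %in% names(tab)) {
    fix <- which(is.na(tab$x_um) & !is.na(tab$mirror_from) & nzchar(tab$mirror_from))
    idx <- match(tab$mirror_from[fix], tab$neuron)
    tab$x_um[fix] <- tab$x_um[idx]
    tab$y_um[fix] <- tab$y_um[idx]
  }
  tab
}

#' Load a connectome from edge and neuron TSV files
#'
#' The edge file has columns `pre`, `post`, `type` (`chem` or `gap`) and
#' `weight`. Multiple synapses between an ordered pair must already be
#' aggregated into one record; the network is analyzed in binarized form
#' with weights kept as metadata.
#'
#' @param edge_tsv path to the edge list TSV.
#' @param neuron_tsv path to the neuron annotation TSV.
#' @param quiet suppress the load log.
#' @return a [connectome()] object.
#' @export
load_connectome <- function(edge_tsv, neuron_tsv, quiet = FALSE) {
  ntab <- read_neuron_table(neuron_tsv)
  if (!file.exists(edge_tsv)) stop_data("edge file not found: %s", edge_tsv)
  ed <- utils::read.delim(edge_tsv, stringsAsFactors = FALSE)
  need <- c("pre", "post", "type")
  miss <- setdiff(need, names(ed))
  if (length(miss) > 0)
    stop_data("edge table missing column(s): %s", paste(miss, collapse = ", "))
  if (!"weight" %in% names(ed)) ed$weight <- 1
  ed$pre <- trimws(ed$pre); ed$post <- trimws(ed$post)
  bad <- setdiff(unique(c(ed$pre, ed$post)), ntab$neuron)
  if (length(bad) > 0) {
    row <- which(ed$pre %in% bad | ed$post %in% bad)[1]
    stop_data("edge row %d references unknown neuron '%s'", row,
              intersect(c(ed$pre[row], ed$post[row]), bad)[1])
  }
  dup <- duplicated(paste(ed$pre, ed$post, ed$type))
  if (any(dup))
    stop_data("duplicate (pre, post, type) record at row %d", which(dup)[1])
  chem <- ed[ed$type == "chem", c("pre", "post", "weight")]
  gp <- ed[ed$type == "gap", , drop = FALSE]
  gap <- data.frame(a = gp$pre, b = gp$post, weight = gp$weight,
                    stringsAsFactors = FALSE)
  cn <- connectome(ntab$neuron, chem = chem, gap = gap, neuron_table = ntab)
  if (!quiet) {
    message(sprintf(
      "loaded %d neurons; %d chemical records, %d gap records, %d connected pairs",
      length(cn$neurons), nrow(cn$chem), nrow(cn$gap), nrow(connected_pairs(cn))))
  }
  cn
}

#' Expand a connectome into its directed edge multiset
#'
#' Chemical edges contribute one directed edge each; each gap junction
#' contributes two (one per direction). A pair carrying both mechanisms in
#' the same direction therefore appears twice, matching the convention that
#' degree sums contributions per mechanism.
#'
#' @param c a connectome.
#' @return data.frame with columns `pre`, `post`, `weight`, `mechanism`.
#' @export
directed_edges <- function(c) {
  stopifnot(inherits(c, "connectome"))
  chem <- c$chem
  gap <- c$gap
  out <- rbind(
    if (nrow(chem) > 0) data.frame(pre = chem$pre, post = chem$post,
                                   weight = chem$weight, mechanism = "chem",
                                   stringsAsFactors = FALSE),
    if (nrow(gap) > 0) data.frame(pre = c(gap$a, gap$b), post = c(gap$b, gap$a),
                                  weight = c(gap$weight, gap$weight),
                                  mechanism = "gap", stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(pre = character(), post = character(),
                      weight = numeric(), mechanism = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Connected unordered neuron pairs
#'
#' A pair counts once regardless of how many mechanisms or directions link
#' it. Flags record whether the pair carries a gap junction, a chemical
#' synapse, and whether its chemical connection is reciprocal.
#'
#' @param c a connectome.
#' @return data.frame with columns `a`, `b`, `has_gap`, `has_chem`,
#'   `chem_reciprocal`.
#' @export
connected_pairs <- function(c) {
  stopifnot(inherits(c, "connectome"))
  chem_key <- if (nrow(c$chem) > 0) pair_key(c$chem$pre, c$chem$post) else character()
  gap_key <- if (nrow(c$gap) > 0) pair_key(c$gap$a, c$gap$b) else character()
  keys <- unique(c(chem_key, gap_key))
  if (length(keys) == 0)
    return(data.frame(a = character(), b = character(), has_gap = logical(),
                      has_chem = logical(), chem_reciprocal = logical(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "|", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1)
  b <- vapply(parts, `[`, "", 2)
  recip <- intersect(chem_key[duplicated(chem_key)], keys)
  data.frame(a = a, b = b,
             has_gap = keys %in% gap_key,
             has_chem = keys %in% chem_key,
             chem_reciprocal = keys %in% recip,
             stringsAsFactors = FALSE)
}

#' Degree sequence of the combined network
#'
#' In-degree counts incoming chemical edges plus one per incident gap
#' junction; out-degree likewise. Total degree is k = k_in + k_out. A pair
#' linked by both mechanisms contributes once per mechanism.
#'
#' @param c a connectome.
#' @return data.frame with columns `neuron`, `k_in`, `k_out`, `k`.
#' @export
degree_sequence <- function(c) {
  stopifnot(inherits(c, "connectome"))
  de <- directed_edges(c)
  k_out <- table(factor(de$pre, levels = c$neurons))
  k_in <- table(factor(de$post, levels = c$neurons))
  data.frame(neuron = c$neurons,
             k_in = as.integer(k_in),
             k_out = as.integer(k_out),
             k = as.integer(k_in) + as.integer(k_out),
             stringsAsFactors = FALSE)
}

#' Label hub neurons by a degree threshold
#'
#' A neuron is a hub when its total degree strictly exceeds `k_threshold`.
#'
#' @param degrees output of [degree_sequence()].
#' @param k_threshold non-negative integer (or -1 to label all neurons hubs).
#' @return `degrees` with an added logical `is_hub` column.
#' @export
label_hubs <- function(degrees, k_threshold) {
  if (!is.numeric(k_threshold) || length(k_threshold) != 1)
    stop_config("k_threshold must be a single number")
  degrees$is_hub <- degrees$k > k_threshold
  degrees
}

#' Classify directed connections by hub status of source and target
#'
#' Every directed connection (gap junctions expanded to both directions) is
#' labeled `rich` (hub to hub), `feed-in` (nonhub to hub), `feed-out` (hub
#' to nonhub) or `peripheral` (nonhub to nonhub).
#'
#' @param c a connectome.
#' @param hubs output of [label_hubs()] covering all neurons of `c`.
#' @return data.frame of directed edges with a `class` column; class counts
#'   are attached as attribute `class_counts`.
#' @export
classify_edges <- function(c, hubs) {
  stopifnot(inherits(c, "connectome"))
  if (!all(c$neurons %in% hubs$neuron))
    stop_data("hub labels do not cover all neurons")
  de <- directed_edges(c)
  is_hub <- hubs$is_hub[match(c$neurons, hubs$neuron)]
  names(is_hub) <- c$neurons
  src <- is_hub[de$pre]
  tgt <- is_hub[de$post]
  de$class <- ifelse(src & tgt, "rich",
              ifelse(!src & tgt, "feed-in",
              ifelse(src & !tgt, "feed-out", "peripheral")))
  attr(de, "class_counts") <- table(factor(
    de$class, levels = c("rich", "feed-in", "feed-out", "peripheral")))
  de
}

#' Write a connectome to edge and neuron TSV files
#'
#' @param c a connectome (with a neuron table for the neuron TSV).
#' @param edge_tsv,neuron_tsv output paths.
#' @return invisibly, the two paths.
#' @export
write_connectome <- function(c, edge_tsv, neuron_tsv) {
  stopifnot(inherits(c, "connectome"))
  ed <- rbind(
    data.frame(pre = c$chem$pre, post = c$chem$post, type = "chem",
               weight = c$chem$weight, stringsAsFactors = FALSE),
    data.frame(pre = c$gap$a, post = c$gap$b, type = "gap",
               weight = c$gap$weight, stringsAsFactors = FALSE))
  utils::write.table(ed, edge_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(c$neuron_table))
    utils::write.table(c$neuron_table, neuron_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(edge_tsv, neuron_tsv))
}
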