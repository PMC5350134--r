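# Network contraction: from a seed gene's exported partner list to the
# stringent core gene set, by merging interaction evidence across a
# BIOGRID-style table and a STRING-links-style table and keeping only
# partners supported by at least `min_channels` independent evidence
# channels (experimental, database, textmining, coexpression).

#' Load and deduplicate a seed gene's interaction-partner list
#'
#' Reads the tabular export of a pathway-analysis query (one row per
#' candidate interacting partner, with official symbol, free-text
#' description, and a delimited synonym list) and collapses rows that
#' refer to the same gene: a row whose symbol or any synonym matches an
#' earlier row's symbol or synonyms is merged into the earlier record,
#' keeping the earlier official symbol.
#'
#' Symbols are canonicalized to uppercase with surrounding whitespace
#' stripped. A synonym collision between two rows that carry distinct
#' official symbols is reported as a warning and the rows are kept
#' separate (distinct official symbols are never silently merged).
#'
#' @param path path to the delimited partner table.
#' @param sep field delimiter (default tab).
#' @param col_symbol,col_description,col_synonyms column names for the
#'   official symbol, description, and synonym list.
#' @param synonym_sep delimiter splitting the synonym field (default ",").
#' @return a data.frame with columns `symbol`, `description` and a
#'   list-column `synonyms` (character vectors, canonicalized, never
#'   containing the record's own symbol); one row per unique gene.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("symbol\tdescription\tsynonyms",
#'              "TP53\ttumor protein p53\tBCC7,TRP53",
#'              "BCC7\tduplicate entry\t"), tf)
#' load_partner_list(tf) # one record, symbol TP53
#' @export
load_partner_list <- function(path, sep = "\t",
                              col_symbol = "symbol",
                              col_description = "description",
                              col_synonyms = "synonyms",
                              synonym_sep = ",") {
  if (!file.exists(path)) stop_format("partner list file not found: %s", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  if (nrow(tab) == 0L) {
    warning("partner list is empty")
    return(data.frame(symbol = character(), description = character(),
                      synonyms = I(list())))
  }
  for (cl in c(col_symbol, col_description, col_synonyms)) {
    if (!cl %in% names(tab))
      stop_format("partner list lacks required column '%s'", cl)
  }

  symbols <- character()       # accepted official symbols, in input order
  descriptions <- character()
  synonyms <- list()
  alias_of <- integer()        # canonical alias -> record index
  names(alias_of) <- character()

  for (i in seq_len(nrow(tab))) {
    sym <- canonical_symbol(tab[[col_symbol]][i])
    if (!nzchar(sym)) next
    syn <- canonical_symbol(strsplit(tab[[col_synonyms]][i], synonym_sep,
                                     fixed = TRUE)[[1]])
    syn <- setdiff(syn[nzchar(syn)], sym)
    hit_sym <- alias_of[sym]
    syn_hits <- unique(alias_of[syn])
    syn_hits <- syn_hits[!is.na(syn_hits)]
    if (!is.na(hit_sym)) {
      # the row's own symbol names an already-seen gene: merge into it
      k <- unname(hit_sym)
      extra <- setdiff(c(sym, syn), symbols[k])
      synonyms[[k]] <- union(synonyms[[k]], extra)
      alias_of[extra[is.na(alias_of[extra])]] <- k
    } else {
      if (length(syn_hits)) {
        # distinct official symbols linked only through shared synonyms:
        # never silently merge, keep both and flag the conflict
        warning(sprintf(
          "synonym collision between official symbols '%s' and '%s'; kept separate",
          paste(unique(symbols[syn_hits]), collapse = "', '"), sym))
      }
      k <- length(symbols) + 1L
      symbols[k] <- sym
      descriptions[k] <- tab[[col_description]][i]
      synonyms[[k]] <- syn
      register <- c(sym, syn[is.na(alias_of[syn])])
      alias_of[register] <- k
    }
  }
  data.frame(symbol = symbols, description = descriptions,
             synonyms = I(synonyms), stringsAsFactors = FALSE)
}

new_edges <- function(partner, channel, source, seed) {
  out <- data.frame(interactor_a = rep_len(canonical_symbol(seed),
                                           length(partner)),
                    interactor_b = partner, channel = channel,
                    source = source, stringsAsFactors = FALSE)
  stopifnot(all(out$channel %in% EVIDENCE_CHANNELS))
  attr(out, "seed") <- canonical_symbol(seed)
  out
}

#' Extract seed-partner interaction edges from a BIOGRID-style table
#'
#' Keeps the rows of a tab-separated interaction table in which one
#' interactor is the seed gene and the other belongs to the candidate
#' partner set. Every retained row becomes one edge carrying the
#' `experimental` evidence channel (BIOGRID experimental systems --
#' two-hybrid, affinity capture, genetic interaction -- are all
#' laboratory evidence).
#'
#' @param path tab-separated interaction table with a header row.
#' @param seed seed gene symbol.
#' @param partners character vector of candidate partner symbols
#'   (canonicalized internally), e.g. `load_partner_list(...)$symbol`.
#' @param col_a,col_b,col_system column names, defaulting to the BIOGRID
#'   TAB dialect.
#' @return a data.frame of edges (`interactor_a` = seed, `interactor_b`,
#'   `channel`, `source`) with the seed stored as an attribute. Rows that
#'   cannot be parsed are skipped with a message naming the row number.
#' @export
parse_biogrid <- function(path, seed, partners,
                          col_a = "Official Symbol Interactor A",
                          col_b = "Official Symbol Interactor B",
                          col_system = "Experimental System") {
  if (!file.exists(path)) stop_format("BIOGRID table not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character", fill = TRUE)
  for (cl in c(col_a, col_b, col_system)) {
    if (!cl %in% names(tab))
      stop_format("BIOGRID table lacks required column '%s'", cl)
  }
  seed <- canonical_symbol(seed)
  partners <- canonical_symbol(partners)
  a <- canonical_symbol(tab[[col_a]])
  b <- canonical_symbol(tab[[col_b]])
  bad <- !nzchar(a) | !nzchar(b)
  if (any(bad)) {
    message(sprintf("skipping %d unparseable BIOGRID row(s): %s",
                    sum(bad), paste(which(bad), collapse = ", ")))
    a <- a[!bad]; b <- b[!bad]
  }
  self <- a == b
  if (any(self & (a == seed)))
    warning(sprintf("%d self-edge(s) on the seed gene ignored", sum(self & a == seed)))
  other <- ifelse(a == seed, b, ifelse(b == seed, a, NA_character_))
  keep <- !is.na(other) & !self & other %in% partners
  if (!any(keep)) {
    warning("no BIOGRID rows link the seed gene to a listed partner")
    return(new_edges(character(), character(), character(), seed))
  }
  new_edges(other[keep], "experimental", "biogrid", seed)
}

# Map the per-channel score columns of a STRING links file onto the
# 4-channel vocabulary. STRING's extra channels (neighborhood, fusion,
# cooccurrence) are genomic-context predictions; they are ignored unless
# the caller opts in, in which case they count as `database` evidence.
STRING_CHANNEL_MAP <- c(experiments = "experimental",
                        experimental = "experimental",
                        database = "database",
                        textmining = "textmining",
                        coexpression = "coexpression")
STRING_EXTRA_CHANNELS <- c("neighborhood", "fusion", "cooccurence",
                           "cooccurrence")

#' Extract seed-partner evidence edges from a STRING-links-style table
#'
#' Reads a whitespace-delimited per-channel score table (the
#' `protein.links.full` dialect: `protein1 protein2` then one score
#' column per evidence channel, scores on a 0-1000 scale), keeps rows
#' linking the seed to a candidate partner, and emits one edge per
#' channel whose score reaches `channel_threshold`.
#'
#' Protein identifiers are mapped to gene symbols either through a
#' two-column mapping table (`id_map`) or, absent one, by stripping a
#' numeric taxon prefix of the form `"9606."`.
#'
#' @param path whitespace-delimited score table with a header line.
#' @param seed,partners as in [parse_biogrid()].
#' @param channel_threshold minimum per-channel score, in (0, 1000];
#'   default 400, the conventional medium-confidence cut.
#' @param id_map optional two-column data.frame or file path (protein id,
#'   gene symbol); rows whose id has no mapping are skipped with a message.
#' @param map_extra_channels if TRUE, STRING's genomic-context channels
#'   (neighborhood, fusion, cooccurrence) count as `database` evidence;
#'   by default they are ignored.
#' @return edge data.frame as in [parse_biogrid()], `source = "string"`.
#' @export
parse_string_links <- function(path, seed, partners, channel_threshold = 400,
                               id_map = NULL, map_extra_channels = FALSE) {
  if (!file.exists(path)) stop_format("STRING links table not found: %s", path)
  if (!is.numeric(channel_threshold) || length(channel_threshold) != 1L ||
      channel_threshold <= 0 || channel_threshold > 1000)
    stop_format("'channel_threshold' must lie in (0, 1000]")
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  score_cols <- intersect(names(STRING_CHANNEL_MAP), names(tab))
  if (!all(c("protein1", "protein2") %in% names(tab)))
    stop_format("STRING table lacks 'protein1'/'protein2' columns")
  need <- c("coexpression", "database", "textmining")
  have_exp <- any(c("experiments", "experimental") %in% names(tab))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) || !have_exp)
    stop_format("STRING table lacks channel column(s): %s",
                paste(c(missing_cols, if (!have_exp) "experiments"),
                      collapse = ", "))
  if (map_extra_channels)
    score_cols <- c(score_cols, intersect(STRING_EXTRA_CHANNELS, names(tab)))

  map_id <- function(x) {
    x <- sub("^[0-9]+\\.", "", as.character(x))
    canonical_symbol(x)
  }
  if (!is.null(id_map)) {
    if (is.character(id_map) && length(id_map) == 1L)
      id_map <- utils::read.table(id_map, header = FALSE,
                                  stringsAsFactors = FALSE,
                                  col.names = c("id", "symbol"))
    lut <- stats::setNames(canonical_symbol(id_map[[2L]]),
                           canonical_symbol(id_map[[1L]]))
    map_id <- function(x) unname(lut[canonical_symbol(x)])
  }

  seed <- canonical_symbol(seed)
  partners <- canonical_symbol(partners)
  p1 <- map_id(tab$protein1)
  p2 <- map_id(tab$protein2)
  unmapped <- is.na(p1) | is.na(p2)
  if (any(unmapped))
    message(sprintf("skipping %d STRING row(s) with no id mapping: %s",
                    sum(unmapped), paste(which(unmapped), collapse = ", ")))
  other <- ifelse(p1 == seed, p2, ifelse(p2 == seed, p1, NA_character_))
  keep <- which(!unmapped & !is.na(other) & p1 != p2 & other %in% partners)

  part <- character(); chan <- character()
  for (i in keep) {
    for (sc in score_cols) {
      s <- suppressWarnings(as.numeric(tab[[sc]][i]))
      if (!is.na(s) && s >= channel_threshold) {
        part <- c(part, other[i])
        chan <- c(chan, if (sc %in% STRING_EXTRA_CHANNELS) "database"
                        else STRING_CHANNEL_MAP[[sc]])
      }
    }
  }
  if (length(part) == 0L) warning("no STRING channel passed the threshold")
  new_edges(part, chan, rep_len("string", length(part)), seed)
}

#' Merge interaction edges into per-partner evidence profiles
#'
#' Unions evidence channels per partner across sources; the same channel
#' reported by several rows or by both databases counts once (a "line of
#' evidence" is a distinct channel, not a row).
#'
#' @param edges edge data.frame (rows may come from [parse_biogrid()] and
#'   [parse_string_links()], concatenated with `rbind`).
#' @return named list, one element per partner: `list(partner, channels,
#'   sources)` with channels and sources sorted character vectors. The
#'   seed attribute of the edges is propagated.
#' @export
merge_evidence <- function(edges) {
  stopifnot(is.data.frame(edges))
  out <- lapply(split(edges, edges$interactor_b), function(d) {
    list(partner = d$interactor_b[1L],
         channels = sort(unique(d$channel)),
         sources = sort(unique(d$source)))
  })
  out <- out[order(names(out))]
  attr(out, "seed") <- attr(edges, "seed")
  out
}

#' Contract an evidence map to the stringent core gene set
#'
#' Partners backed by fewer than `min_channels` distinct evidence
#' channels are filtered out; the survivors, sorted lexicographically,
#' form the core gene set. The seed itself is excluded regardless of
#' evidence.
#'
#' @param evidence_map output of [merge_evidence()].
#' @param seed seed gene symbol; defaults to the map's seed attribute.
#' @param min_channels minimum number of distinct evidence channels
#'   (default 2, the "at least two independent lines of evidence" rule).
#' @return an object of class `core_gene_set`: `list(seed, genes,
#'   provenance, min_channels)` where `provenance` keeps every evaluated
#'   partner's profile plus a `kept` flag.
#' @export
contract_network <- function(evidence_map, seed = attr(evidence_map, "seed"),
                             min_channels = 2L) {
  if (is.null(seed)) stop_format("seed gene must be supplied")
  if (!is.numeric(min_channels) || min_channels < 1)
    stop_format("'min_channels' must be >= 1")
  seed <- canonical_symbol(seed)
  prov <- lapply(evidence_map, function(pr) {
    pr$kept <- length(pr$channels) >= min_channels && pr$partner != seed
    pr
  })
  genes <- sort(names(prov)[vapply(prov, `[[`, logical(1L), "kept")])
  if (length(genes) == 0L)
    warning("no partner reaches the evidence threshold; core gene set is empty")
  structure(list(seed = seed, genes = genes, provenance = prov,
                 min_channels = as.integer(min_channels)),
            class = "core_gene_set")
}

#' @export
print.core_gene_set <- function(x, ...) {
  cat(sprintf("Core gene set for seed %s (>= %d evidence channels): %d gene(s)\n",
              x$seed, x$min_channels, length(x$genes)))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a core-gene-set provenance table
#'
#' The provenance TSV lists every evaluated partner with its evidence
#' channels, sources and kept/dropped flag; the seed and threshold are
#' recorded in `#`-prefixed header lines so [read_provenance()]
#' reconstructs the identical `core_gene_set`.
#'
#' @param core a `core_gene_set`.
#' @param path output path.
#' @return `write_provenance` returns `path` invisibly; `read_provenance`
#'   returns the reconstructed `core_gene_set`.
#' @export
write_provenance <- function(core, path) {
  stopifnot(inherits(core, "core_gene_set"))
  rows <- vapply(core$provenance, function(pr) {
    paste(pr$partner, paste(pr$channels, collapse = ","),
          paste(pr$sources, collapse = ","),
          if (pr$kept) "kept" else "dropped", sep = "\t")
  }, character(1L))
  writeLines(c(sprintf("# seed=%s", core$seed),
               sprintf("# min_channels=%d", core$min_channels),
               "gene\tchannels\tsources\tstatus",
               unname(rows)), path)
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  seed <- sub("^# seed=", "", hdr[startsWith(hdr, "# seed=")])
  min_channels <- as.integer(sub("^# min_channels=", "",
                                 hdr[startsWith(hdr, "# min_channels=")]))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  prov <- lapply(seq_len(nrow(tab)), function(i) {
    list(partner = tab$gene[i],
         channels = strsplit(tab$channels[i], ",", fixed = TRUE)[[1L]],
         sources = strsplit(tab$sources[i], ",", fixed = TRUE)[[1L]],
         kept = tab$status[i] == "kept")
  })
  names(prov) <- tab$gene
  prov <- prov[order(names(prov))]
  genes <- sort(tab$gene[tab$status == "kept"])
  structure(list(seed = seed, genes = genes, provenance = prov,
                 min_channels = min_channels),
            class = "core_gene_set")
}
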