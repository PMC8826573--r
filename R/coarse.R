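## Coarse-graining of contacts onto strand/loop element pairs, class
## averaging with SEM, normalized difference maps, per-residue open-book
## scores and flareplot export.

.element_axis <- c("Nterm", "A", "AB", "B", "BC", "C", "CD", "D", "DE",
                   "E", "EF", "F", "FG", "G", "Cterm")

#' Coarse-grain a contact table onto element pairs
#'
#' For each interaction kind, the occurrence ratio of an element pair
#' (ea, eb) is the fraction of frames in which at least one contact of
#' that kind joins a residue labeled ea in domain a to a residue labeled
#' eb in domain b (frame union over residue pairs, not a sum -- the
#' flareplot edge is an existence statistic).
#'
#' @param table contact records from [trajectoryContacts()].
#' @param map_a,map_b [ElementMap]s for the two domains.
#' @param frame_count total frames (defaults to the table attribute).
#' @param system system identifier stored in the result.
#' @return named list of [ContactFrequencyTable], one per kind present
#'   in `.contact_kinds` (all four, zero matrices when absent).
#' @export
coarseGrain <- function(table, map_a, map_b,
                        frame_count = attr(table, "frame_count"),
                        system = "system") {
  if (is.null(frame_count) || frame_count < 1)
    stop("frame_count must be >= 1")
  ea <- elementOf(map_a, table$residue_a)
  eb <- elementOf(map_b, table$residue_b)
  if (anyNA(ea)) {
    stop("residue without element label in domain a: ",
         table$residue_a[which(is.na(ea))[1]])
  }
  if (anyNA(eb)) {
    stop("residue without element label in domain b: ",
         table$residue_b[which(is.na(eb))[1]])
  }
  out <- list()
  for (k in .contact_kinds) {
    m <- matrix(0, length(.element_axis), length(.element_axis),
                dimnames = list(.element_axis, .element_axis))
    rows <- table$kind == k
    if (any(rows)) {
      key <- paste(ea[rows], eb[rows])
      cnt <- tapply(table$frame[rows], key,
                    function(f) length(unique(f)))
      for (nm in names(cnt)) {
        p <- strsplit(nm, " ", fixed = TRUE)[[1]]
        m[p[1], p[2]] <- cnt[[nm]] / frame_count
      }
    }
    out[[k]] <- methods::new("ContactFrequencyTable", system = system,
                             kind = k, ratios = m)
  }
  out
}

#' Average frequency tables across the systems of an interface class
#'
#' Computes, per element pair, the mean occurrence ratio and the standard
#' error of the mean (sample sd / sqrt(n); 0 for a single system) over
#' member systems. Element pairs missing from a system count as ratio 0:
#' the absence of a contact is an observation, not missing data.
#'
#' @param tables list of [ContactFrequencyTable] of one kind.
#' @param class_id class identifier (e.g. "CH3-CH3").
#' @return a [ClassSummary].
#' @export
classAverage <- function(tables, class_id = "class") {
  if (!length(tables)) stop("need at least one frequency table")
  kinds <- unique(vapply(tables, function(t) t@kind, ""))
  if (length(kinds) != 1)
    stop("tables mix contact kinds: ", paste(kinds, collapse = ", "))
  stack <- simplify2array(lapply(tables, function(t) t@ratios))
  n <- length(tables)
  mu <- apply(stack, c(1, 2), mean)
  sem <- if (n == 1) {
    matrix(0, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  } else {
    apply(stack, c(1, 2), stats::sd) / sqrt(n)
  }
  methods::new("ClassSummary", class_id = class_id, kind = kinds,
               mean = mu, sem = sem, n_systems = as.integer(n))
}

#' Normalized difference map between two interface classes
#'
#' Entry-wise (mean1 - mean2) divided by the largest mean occurrence
#' ratio over both classes, so the map lies in [-1, 1] and the color
#' scale is normalized to the most frequent contact in either class.
#' Antisymmetric under swapping the classes.
#'
#' @param s1,s2 [ClassSummary] objects of the same kind.
#' @return a [DifferenceMap].
#' @export
differenceMap <- function(s1, s2) {
  if (s1@kind != s2@kind)
    stop("summaries have different kinds: ", s1@kind, " vs ", s2@kind)
  if (!identical(dimnames(s1@mean), dimnames(s2@mean)))
    stop("summaries have different element label sets")
  norm <- max(s1@mean, s2@mean)
  if (norm <= 0)
    stop("normalizer undefined: both classes have all-zero ratios")
  methods::new("DifferenceMap", kind = s1@kind,
               delta = (s1@mean - s2@mean) / norm,
               normalizer = norm,
               classes = c(s1@class_id, s2@class_id))
}

#' Per-residue open-book contact scores
#'
#' For every residue (in both domains), the sum over its distinct
#' partner residues of the occurrence ratio of that residue pair --
#' a duration-weighted interdomain partner count, the quantity used to
#' shade the open-book interface rendering. A residue in permanent
#' contact with two partners scores 2.0.
#'
#' @param table contact records from [trajectoryContacts()].
#' @param kind optional kind filter (e.g. "saltbridge").
#' @param frame_count total frames (defaults to the table attribute).
#' @return named numeric vector over residues of both domains.
#' @export
openBookCounts <- function(table, kind = NULL,
                           frame_count = attr(table, "frame_count")) {
  if (is.null(frame_count) || frame_count < 1)
    stop("frame_count must be >= 1")
  if (!is.null(kind)) table <- table[table$kind == kind, , drop = FALSE]
  if (!nrow(table)) return(stats::setNames(numeric(0), character(0)))
  pair <- paste(table$residue_a, table$residue_b, sep = "|")
  ratio <- tapply(table$frame, pair, function(f) length(unique(f))) /
    frame_count
  ab <- strsplit(names(ratio), "|", fixed = TRUE)
  res_a <- vapply(ab, `[`, "", 1)
  res_b <- vapply(ab, `[`, "", 2)
  sc_a <- tapply(as.vector(ratio), res_a, sum)
  sc_b <- tapply(as.vector(ratio), res_b, sum)
  out <- c(sc_a, sc_b)
  stats::setNames(as.vector(out), names(out))
}

#' Export a frequency table as flareplot JSON
#'
#' Writes `{"edges": [{"name1": "a_AB", "name2": "b_G", "weight": r},
#' ...]}` with one edge per nonzero element pair, in stable row-major
#' order; edge weight is the occurrence ratio.
#'
#' @param table a [ContactFrequencyTable].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportFlareJSON <- function(table, path) {
  r <- table@ratios
  nz <- which(r > 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  edges <- lapply(seq_len(nrow(nz)), function(k) {
    list(name1 = paste0("a_", rownames(r)[nz[k, 1]]),
         name2 = paste0("b_", colnames(r)[nz[k, 2]]),
         weight = unname(r[nz[k, 1], nz[k, 2]]))
  })
  jsonlite::write_json(list(edges = edges), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a flareplot JSON into a ratio matrix
#'
#' @param path a file written by [exportFlareJSON()].
#' @param kind,system metadata for the rebuilt table.
#' @return a [ContactFrequencyTable].
#' @export
readFlareJSON <- function(path, kind = "vdw", system = "imported") {
  j <- jsonlite::read_json(path)
  m <- matrix(0, length(.element_axis), length(.element_axis),
              dimnames = list(.element_axis, .element_axis))
  for (e in j$edges) {
    m[sub("^a_", "", e$name1), sub("^b_", "", e$name2)] <- e$weight
  }
  methods::new("ContactFrequencyTable", system = system, kind = kind,
               ratios = m)
}

#' Write a frequency table, summary or difference map as TSV
#'
#' Matrices are written with element row/column names; summaries as
#' long-format element-pair rows with mean and SEM.
#'
#' @param x a [ContactFrequencyTable], [ClassSummary] or [DifferenceMap].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCoarseTSV <- function(x, path) {
  if (methods::is(x, "ContactFrequencyTable")) {
    utils::write.table(x@ratios, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else if (methods::is(x, "DifferenceMap")) {
    utils::write.table(x@delta, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else if (methods::is(x, "ClassSummary")) {
    df <- expand.grid(element_a = rownames(x@mean),
                      element_b = colnames(x@mean),
                      stringsAsFactors = FALSE)
    df$mean <- as.vector(x@mean)
    df$sem <- as.vector(x@sem)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}

#' Per-element marginal contact frequencies
#'
#' Sums mean occurrence ratios over all partners of each element,
#' separately for the two domains -- the per strand/loop quantities shown
#' in class-comparison barplots.
#'
#' @param summary a [ClassSummary].
#' @return data.frame with columns domain, element, total_ratio.
#' @export
elementMarginals <- function(summary) {
  data.frame(
    domain = rep(c("a", "b"), each = nrow(summary@mean)),
    element = c(rownames(summary@mean), colnames(summary@mean)),
    total_ratio = c(rowSums(summary@mean), colSums(summary@mean)),
    row.names = NULL, stringsAsFactors = FALSE)
}
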