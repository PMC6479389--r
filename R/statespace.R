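# Tobacco-use state machine: use categories, duration memory, edge catalogue.

# Category codes. "Current" categories are product-use states occupied during
# an interval; "former" categories carry use history through the duration
# counters. FORMER_ALL marks simultaneous cessation of both products (from
# dual use); sequential quitters keep the category of the last product quit.
.CATEGORIES <- c("NEVER", "CUR_CIG", "CUR_MST", "DUAL",
                 "FORMER_CIG", "FORMER_MST", "FORMER_DUAL", "FORMER_ALL")
.SMOKING_CATS <- c("CUR_CIG", "DUAL")
.MST_CATS <- c("CUR_MST", "DUAL")

#' Tobacco-use category codes
#'
#' The eight use categories through which cohort members move: never-user,
#' current cigarette smoker, current moist-smokeless-tobacco (MST) user,
#' dual user, and the corresponding former-use categories. Duration memory
#' (years smoked, years since quitting, years of MST use) is carried
#' separately by the expanded state, so a "former MST user" who used to
#' smoke is distinguished from one who never did by the counters, not by
#' the category code.
#'
#' @return Character vector of the eight category codes.
#' @export
use_categories <- function() .CATEGORIES

#' Construct an edge catalogue
#'
#' An edge catalogue lists the permitted one-step transitions between use
#' categories. Self-loops are never listed: remaining in a category is the
#' residual probability after all outgoing transitions. Two rows may carry
#' class `"diversion"`: these are the would-be-smoker (never-user initiates
#' MST instead of cigarettes) and would-be-quitter (smoker switches to MST
#' instead of quitting) flows, which share endpoints with ordinary edges and
#' are materialised by [derive_modified_table()], not by independent rates.
#'
#' @param edges data.frame with columns `from`, `to`, `label`, `class`.
#' @return The validated catalogue, class `edge_catalogue`.
#' @seealso [default_edge_catalogue()]
#' @export
edge_catalogue <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "to", "label", "class")
  if (!all(need %in% names(edges)))
    stop("edge catalogue needs columns: ", paste(need, collapse = ", "))
  bad <- !(edges$from %in% .CATEGORIES) | !(edges$to %in% .CATEGORIES)
  if (any(bad))
    stop("unknown category in edges: ",
         paste(unique(c(edges$from[bad], edges$to[bad])), collapse = ", "))
  if (any(edges$from == edges$to))
    stop("self-loops are implicit (residual stay probability); remove ",
         paste(edges$from[edges$from == edges$to], collapse = ", "))
  if (anyDuplicated(edges[, c("from", "to", "label")]))
    stop("duplicated (from, to, label) rows in edge catalogue")
  rownames(edges) <- NULL
  class(edges) <- c("edge_catalogue", "data.frame")
  edges
}

#' Default edge catalogue
#'
#' The default transition structure between never use, cigarette smoking,
#' MST use and dual use: initiation to either product, switching, dual
#' uptake, resolution of dual use to either exclusive product, cessation
#' from every current-use category, relapse edges (present in the catalogue
#' but conventionally given rate zero, as behavioural data on former-user
#' relapse is typically too sparse to estimate), and the two diversion
#' flows used only when deriving a Modified-Case table.
#'
#' @return An [edge_catalogue()].
#' @export
default_edge_catalogue <- function() {
  edge_catalogue(data.frame(
    from = c("NEVER", "NEVER", "CUR_CIG", "CUR_CIG", "CUR_CIG",
             "CUR_MST", "CUR_MST", "DUAL", "DUAL", "DUAL",
             "FORMER_CIG", "FORMER_MST", "FORMER_ALL", "FORMER_ALL",
             "NEVER", "CUR_CIG"),
    to = c("CUR_CIG", "CUR_MST", "CUR_MST", "DUAL", "FORMER_CIG",
           "DUAL", "FORMER_MST", "CUR_MST", "CUR_CIG", "FORMER_ALL",
           "CUR_CIG", "CUR_MST", "CUR_CIG", "CUR_MST",
           "CUR_MST", "CUR_MST"),
    label = c("initiation_cig", "initiation_mst", "switching",
              "dual_uptake", "cessation_cig",
              "dual_uptake_mst", "cessation_mst",
              "dual_to_mst", "dual_to_cig", "cessation_dual",
              "relapse_cig", "relapse_mst", "relapse_all_cig",
              "relapse_all_mst",
              "would_be_smoker", "would_be_quitter"),
    class = c("initiation", "initiation", "switching",
              "switching", "cessation",
              "switching", "cessation",
              "switching", "switching", "cessation",
              "relapse", "relapse", "relapse", "relapse",
              "diversion", "diversion"),
    stringsAsFactors = FALSE
  ))
}

# rows of a catalogue that describe real per-step flows (diversions excluded)
.flow_edges <- function(catalogue) {
  catalogue[catalogue$class != "diversion", , drop = FALSE]
}

.has_edge <- function(catalogue, from, to) {
  any(catalogue$from == from & catalogue$to == to & catalogue$class != "diversion")
}

#' Construct an expanded state
#'
#' An expanded state is a use category plus duration memory in 5-year bins:
#' `ysm` bins of cigarette smoking, `yqsm` bins since quitting cigarettes,
#' `mst` bins of MST use and `yqmst` bins since quitting MST. The counters
#' never decrease, and time-since-quitting counters require a corresponding
#' use history.
#'
#' @param category one of [use_categories()].
#' @param ysm,yqsm,mst,yqmst non-negative integer bin counts.
#' @return A list of class `expanded_state`.
#' @export
expanded_state <- function(category, ysm = 0L, yqsm = 0L, mst = 0L, yqmst = 0L) {
  if (!category %in% .CATEGORIES) stop("unknown category: ", category)
  d <- c(ysm = ysm, yqsm = yqsm, mst = mst, yqmst = yqmst)
  if (any(d < 0) || any(d != floor(d))) stop("duration bins must be non-negative integers")
  if (yqsm > 0 && ysm == 0) stop("yqsm > 0 requires ysm > 0")
  if (yqmst > 0 && mst == 0) stop("yqmst > 0 requires mst > 0")
  structure(list(category = category, ysm = as.integer(ysm),
                 yqsm = as.integer(yqsm), mst = as.integer(mst),
                 yqmst = as.integer(yqmst)),
            class = "expanded_state")
}

#' @export
print.expanded_state <- function(x, ...) {
  cat(sprintf("<%s ysm=%d yqsm=%d mst=%d yqmst=%d>\n",
              x$category, x$ysm, x$yqsm, x$mst, x$yqmst))
  invisible(x)
}

# Vectorised duration bookkeeping for one 5-year interval occupied in
# category `cat`: smoking categories accrue ysm, MST categories accrue mst
# (dual users accrue both), anyone with a smoking history who is not
# currently smoking accrues yqsm, and likewise for yqmst. `max_bins` caps
# each counter so covariates stay within the fitted mortality-data range.
.advance_durations <- function(cat, ysm, yqsm, mst, yqmst, max_bins = Inf) {
  smoking <- cat %in% .SMOKING_CATS
  using_mst <- cat %in% .MST_CATS
  list(
    ysm   = pmin(ysm + smoking, max_bins),
    yqsm  = pmin(yqsm + (ysm > 0L & !smoking), max_bins),
    mst   = pmin(mst + using_mst, max_bins),
    yqmst = pmin(yqmst + (mst > 0L & !using_mst), max_bins)
  )
}

#' Advance an expanded state by one 5-year step
#'
#' Durations accrue according to the category occupied during the interval
#' (the source category); the category then becomes the edge target, or is
#' unchanged when no edge is taken. Taking an edge that is not in the
#' catalogue is an error.
#'
#' @param state an [expanded_state()].
#' @param edge `NULL` to stay, or a length-2 character vector
#'   `c(from, to)` naming a catalogue edge with `from == state$category`.
#' @param catalogue an [edge_catalogue()].
#' @param max_bins cap on each duration counter (bins).
#' @return The new `expanded_state`.
#' @export
step_state <- function(state, edge = NULL,
                       catalogue = default_edge_catalogue(),
                       max_bins = Inf) {
  stopifnot(inherits(state, "expanded_state"))
  target <- state$category
  if (!is.null(edge)) {
    if (length(edge) != 2L)
      stop("edge must be c(from, to)")
    if (edge[1L] != state$category)
      stop("edge (", edge[1L], ", ", edge[2L], ") does not leave the ",
           "occupied category ", state$category)
    if (!.has_edge(catalogue, edge[1L], edge[2L]))
      stop("illegal transition (", edge[1L], ", ", edge[2L],
           "): not in the edge catalogue")
    target <- edge[2L]
  }
  d <- .advance_durations(state$category, state$ysm, state$yqsm,
                          state$mst, state$yqmst, max_bins)
  expanded_state(target, d$ysm, d$yqsm, d$mst, d$yqmst)
}

#' Count reachable expanded states
#'
#' Breadth-first enumeration of the distinct (category, durations) states
#' reachable from a never-user over a simulation horizon, under a given
#' catalogue and duration cap. Useful to report the effective size of the
#' expanded state space behind the category-level diagram.
#'
#' @param catalogue an [edge_catalogue()].
#' @param start_age,end_age horizon in years (5-year steps).
#' @param max_bins duration cap in 5-year bins.
#' @return Integer count of distinct expanded states visited.
#' @export
count_reachable_states <- function(catalogue = default_edge_catalogue(),
                                   start_age = 13, end_age = 103,
                                   max_bins = 12L) {
  flows <- .flow_edges(catalogue)
  cur <- data.table::data.table(cat = "NEVER", ysm = 0L, yqsm = 0L,
                                mst = 0L, yqmst = 0L)
  seen <- data.table::copy(cur)
  n_steps <- floor((end_age - start_age) / 5)
  for (k in seq_len(n_steps)) {
    moved <- merge(cur, data.table::as.data.table(flows[, c("from", "to")]),
                   by.x = "cat", by.y = "from", allow.cartesian = TRUE)
    stay <- data.table::copy(cur)[, "to" := cat]
    nxt <- rbind(moved, stay)
    d <- .advance_durations(nxt$cat, nxt$ysm, nxt$yqsm, nxt$mst, nxt$yqmst,
                            max_bins)
    nxt <- data.table::data.table(cat = nxt$to, ysm = as.integer(d$ysm),
                                  yqsm = as.integer(d$yqsm),
                                  mst = as.integer(d$mst),
                                  yqmst = as.integer(d$yqmst))
    cur <- unique(nxt)
    seen <- unique(rbind(seen, cur))
  }
  nrow(seen)
}

#' Read or write an edge catalogue as CSV
#'
#' Columns: `from_category,to_category,label,class`.
#'
#' @param path file path.
#' @param catalogue an [edge_catalogue()] (for writing).
#' @return `read_edge_catalogue()` returns an [edge_catalogue()];
#'   `write_edge_catalogue()` returns `path` invisibly.
#' @export
read_edge_catalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "from_category"] <- "from"
  names(df)[names(df) == "to_category"] <- "to"
  if (is.null(df$class)) df$class <- "other"
  edge_catalogue(df)
}

#' @rdname read_edge_catalogue
#' @export
write_edge_catalogue <- function(catalogue, path) {
  out <- data.frame(from_category = catalogue$from,
                    to_category = catalogue$to,
                    label = catalogue$label,
                    class = catalogue$class)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
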