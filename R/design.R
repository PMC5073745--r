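#' @import methods
#' @importFrom stats model.matrix pf pt phyper pnorm rnorm runif sd t.test
#'   dist hclust p.adjust setNames
#' @importFrom utils read.delim write.table combn head
NULL

.TIME_LEVELS <- c(0, 0.5, 2, 4, 8, 24)
.TREATMENTS <- c("control", "PHN")
.DYES <- c("red", "green")

#' KineticDesign: a dye-switch kinetic experimental design
#'
#' Represents the layout of a two-colour dye-swap time-course experiment:
#' which (time, treatment) cell was hybridised on which array with which
#' dye, and which pairs of cells are directly compared by dye-swapped
#' array pairs. The default design reconstructs an 11-cell kinetic layout
#' (a shared t = 0 baseline plus five timepoints under two treatments)
#' probed by 14 comparisons, each replicated on two arrays with opposite
#' dye orientations: 28 arrays and 56 observations in all.
#'
#' @slot observations data.frame with one row per observation and columns
#'   `obs_id`, `array_id`, `dye`, `time_h`, `treatment`. Row order is the
#'   canonical observation order used by [designMatrix()].
#' @slot comparisons data.frame with one row per dye-swapped comparison and
#'   columns `time_a`, `treatment_a`, `time_b`, `treatment_b`, `array_1`,
#'   `array_2`.
#'
#' @seealso [buildDefaultDesign()], [designMatrix()], [residualDf()]
#' @export
setClass("KineticDesign",
  representation(observations = "data.frame", comparisons = "data.frame"))

setValidity("KineticDesign", function(object) {
  obs <- object@observations
  msgs <- character()
  need <- c("obs_id", "array_id", "dye", "time_h", "treatment")
  if (!all(need %in% names(obs)))
    return(paste("observations must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(obs$obs_id))
    msgs <- c(msgs, "duplicate obs_id")
  if (!all(obs$dye %in% .DYES))
    msgs <- c(msgs, "dye must be 'red' or 'green'")
  if (!all(obs$treatment %in% .TREATMENTS))
    msgs <- c(msgs, "treatment must be 'control' or 'PHN'")
  if (any(obs$time_h == 0 & obs$treatment != "control"))
    msgs <- c(msgs, "time 0 is the shared baseline and must be 'control'")
  byArray <- split(obs$dye, obs$array_id)
  if (!all(vapply(byArray, function(d)
        length(d) == 2L && setequal(d, .DYES), logical(1))))
    msgs <- c(msgs, "each array must carry exactly two observations with opposite dyes")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn KineticDesign observation table accessor
#' @param x,object a `KineticDesign`
#' @export
observations <- function(x) {
  stopifnot(is(x, "KineticDesign"))
  x@observations
}

#' @describeIn KineticDesign comparison table accessor
#' @export
comparisons <- function(x) {
  stopifnot(is(x, "KineticDesign"))
  x@comparisons
}

#' @describeIn KineticDesign distinct (time, treatment) cells, as a
#'   data.frame sorted by time then treatment
#' @export
designCells <- function(x) {
  obs <- observations(x)
  cells <- unique(obs[, c("time_h", "treatment")])
  cells <- cells[order(cells$time_h, cells$treatment), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' @describeIn KineticDesign number of arrays
#' @export
nArrays <- function(x) length(unique(observations(x)$array_id))

setMethod("show", "KineticDesign", function(object) {
  obs <- object@observations
  cells <- designCells(object)
  cat("KineticDesign:", nrow(obs), "observations on", nArrays(object),
      "dye-swap arrays\n")
  cat(" ", nrow(cells), "time x treatment cells;",
      nrow(object@comparisons), "comparisons\n")
  cat("  time levels (h):", paste(sort(unique(obs$time_h)), collapse = ", "), "\n")
})

#' Construct the default 28-array dye-switch kinetic design
#'
#' Builds the canonical layout: at each of the five timepoints (0.5, 2, 4,
#' 8, 24 h) a treated-vs-control comparison; a consecutive-time chain
#' through the treated arm starting from the shared t = 0 baseline
#' (0 -> 0.5 -> 2 -> 4 -> 8 -> 24 h); and a consecutive-time chain through
#' the control arm (0.5 -> 2 -> 4 -> 8 -> 24 h). That is 14 comparisons,
#' each hybridised on two arrays with swapped dye orientations, giving 28
#' arrays and 56 observations over 11 distinct cells. With this layout the
#' additive model has 22 residual degrees of freedom and the interaction
#' model 18.
#'
#' @return a [KineticDesign-class] object
#' @examples
#' d <- buildDefaultDesign()
#' nrow(observations(d))  # 56
#' residualDf(d, "additive")     # 22
#' residualDf(d, "interaction")  # 18
#' @export
buildDefaultDesign <- function() {
  tp <- .TIME_LEVELS[-1]
  cmp <- data.frame(
    time_a = numeric(0), treatment_a = character(0),
    time_b = numeric(0), treatment_b = character(0))
  # treated vs control at each timepoint
  for (t in tp)
    cmp <- rbind(cmp, data.frame(time_a = t, treatment_a = "PHN",
                                 time_b = t, treatment_b = "control"))
  # consecutive-time chain, treated arm, anchored at the shared baseline
  chain <- rbind(data.frame(time_h = 0, treatment = "control"),
                 data.frame(time_h = tp, treatment = "PHN"))
  for (i in seq_len(nrow(chain) - 1L))
    cmp <- rbind(cmp, data.frame(
      time_a = chain$time_h[i + 1L], treatment_a = chain$treatment[i + 1L],
      time_b = chain$time_h[i],      treatment_b = chain$treatment[i]))
  # consecutive-time chain, control arm
  for (i in seq_len(length(tp) - 1L))
    cmp <- rbind(cmp, data.frame(time_a = tp[i + 1L], treatment_a = "control",
                                 time_b = tp[i],      treatment_b = "control"))
  cmp$array_1 <- 2L * seq_len(nrow(cmp)) - 1L
  cmp$array_2 <- 2L * seq_len(nrow(cmp))
  obs <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
    data.frame(
      array_id = c(cmp$array_1[i], cmp$array_1[i], cmp$array_2[i], cmp$array_2[i]),
      dye = c("red", "green", "green", "red"),
      time_h = c(cmp$time_a[i], cmp$time_b[i], cmp$time_a[i], cmp$time_b[i]),
      treatment = c(cmp$treatment_a[i], cmp$treatment_b[i],
                    cmp$treatment_a[i], cmp$treatment_b[i]))
  }))
  obs <- obs[order(obs$array_id, match(obs$dye, .DYES)), , drop = FALSE]
  obs <- data.frame(obs_id = sprintf("a%02d_%s", obs$array_id, obs$dye), obs,
                    stringsAsFactors = FALSE)
  rownames(obs) <- NULL
  new("KineticDesign", observations = obs, comparisons = cmp)
}

# Greedily keep columns that increase numerical rank; preserves column order.
.rankReduce <- function(X, tol = 1e-10) {
  keep <- logical(ncol(X))
  r <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- X[, c(which(keep), j), drop = FALSE]
    rj <- qr(cand, tol = tol)$rank
    if (rj > r) { keep[j] <- TRUE; r <- rj }
  }
  X[, keep, drop = FALSE]
}

#' Build the model matrix for the additive or interaction model
#'
#' The per-gene models are `Y = mu + alpha_t + beta_p + delta_a + eps`
#' (additive) and `Y = mu + alpha_t + beta_p + gamma_tp + delta_a + eps`
#' (interaction): fixed time, treatment and array effects, with an
#' interaction between time and treatment in the richer model. Indicator
#' columns are reference-reduced (first time level, control treatment,
#' first array dropped); interaction indicators are built only for
#' observed non-reference cells and then reduced to a full-rank set by
#' numerical rank, because a cell missing from the design (here t = 0
#' under treatment) makes one interaction column collinear with the
#' treatment main effect. No dye coefficient is included: the dye enters
#' the observation index only.
#'
#' @param design a [KineticDesign-class]
#' @param variant `"additive"` or `"interaction"`
#' @return numeric indicator matrix, rows in `observations(design)` order
#' @export
designMatrix <- function(design, variant = c("additive", "interaction")) {
  variant <- match.arg(variant)
  obs <- observations(design)
  cells <- designCells(design)
  if (nrow(cells) < 2L || nArrays(design) < 2L)
    stop("invalid design: need at least 2 cells and 2 arrays")
  tlev <- sort(unique(obs$time_h))
  df <- data.frame(
    time = factor(obs$time_h, levels = tlev),
    treatment = factor(obs$treatment, levels = .TREATMENTS),
    array = factor(obs$array_id, levels = sort(unique(obs$array_id))))
  X <- model.matrix(~ time + treatment + array, df)
  if (variant == "interaction") {
    trtIdx <- as.integer(df$treatment == .TREATMENTS[2L])
    gcells <- cells[cells$time_h != tlev[1L] & cells$treatment == .TREATMENTS[2L], ,
                    drop = FALSE]
    G <- sapply(seq_len(nrow(gcells)), function(i)
      as.integer(obs$time_h == gcells$time_h[i]) * trtIdx)
    if (length(G)) {
      G <- matrix(G, nrow = nrow(obs))
      colnames(G) <- sprintf("time%s:treatmentPHN", gcells$time_h)
      X <- .rankReduce(cbind(X, G))
    }
  }
  rownames(X) <- obs$obs_id
  X
}

#' Residual degrees of freedom of a model on a design
#'
#' Computed as the number of observations minus the numerical rank of the
#' model matrix, never from a closed-form count. On the default design this
#' gives 22 for the additive and 18 for the interaction model, so the
#' nested F-test has 4 numerator and 18 denominator degrees of freedom.
#'
#' @inheritParams designMatrix
#' @return integer residual degrees of freedom
#' @export
residualDf <- function(design, variant = c("additive", "interaction")) {
  X <- designMatrix(design, variant)
  r <- qr(X)$rank
  df <- nrow(X) - r
  if (df <= 0L)
    stop("no residual degrees of freedom: model matrix rank equals observation count")
  as.integer(df)
}

#' Write / read a design table
#'
#' Tab-delimited, one row per observation with columns `obs_id`,
#' `array_id`, `dye`, `time_h`, `treatment`. Writing then reading
#' round-trips the design exactly.
#'
#' @param design a [KineticDesign-class]
#' @param path file path
#' @return `readDesign` returns a [KineticDesign-class]; comparisons are
#'   reconstructed from the dye-swapped array structure.
#' @export
writeDesign <- function(design, path) {
  write.table(observations(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  obs <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(obs_id = "character", array_id = "integer",
                                   dye = "character", time_h = "numeric",
                                   treatment = "character"))
  new("KineticDesign", observations = obs,
      comparisons = .inferComparisons(obs))
}

# Pair arrays probing the same unordered cell pair with opposite orientations.
.inferComparisons <- function(obs) {
  cellKey <- function(t, p) paste(t, p, sep = "|")
  byArray <- split(obs, obs$array_id)
  info <- do.call(rbind, lapply(byArray, function(a) {
    a <- a[order(match(a$dye, .DYES)), ]  # red first
    data.frame(array_id = a$array_id[1L],
               red = cellKey(a$time_h[1L], a$treatment[1L]),
               green = cellKey(a$time_h[2L], a$treatment[2L]))
  }))
  info$pair <- ifelse(info$red < info$green,
                      paste(info$red, info$green, sep = "~"),
                      paste(info$green, info$red, sep = "~"))
  cmp <- do.call(rbind, lapply(split(info, info$pair), function(g) {
    g <- g[order(g$array_id), ]
    a <- strsplit(g$red[1L], "|", fixed = TRUE)[[1L]]
    b <- strsplit(g$green[1L], "|", fixed = TRUE)[[1L]]
    data.frame(time_a = as.numeric(a[1L]), treatment_a = a[2L],
               time_b = as.numeric(b[1L]), treatment_b = b[2L],
               array_1 = g$array_id[1L],
               array_2 = if (nrow(g) > 1L) g$array_id[2L] else NA_integer_)
  }))
  rownames(cmp) <- NULL
  cmp[order(cmp$array_1), , drop = FALSE]
}

#' Remove a dye-swapped comparison from a design
#'
#' Drops both arrays of one comparison (by row index in
#' `comparisons(design)`), for sensitivity analyses of the residual
#' degrees of freedom.
#'
#' @param design a [KineticDesign-class]
#' @param i comparison row index
#' @export
dropComparison <- function(design, i) {
  cmp <- comparisons(design)
  stopifnot(i >= 1L, i <= nrow(cmp))
  arrays <- c(cmp$array_1[i], cmp$array_2[i])
  obs <- observations(design)
  new("KineticDesign",
      observations = obs[!obs$array_id %in% arrays, , drop = FALSE],
      comparisons = cmp[-i, , drop = FALSE])
}

#' Remove a single array from a design
#'
#' Drops one array and its dye-swapped pair of observations (so the
#' observation count falls by 2); the comparison it replicated keeps its
#' remaining orientation. Ranks and residual dfs are always recomputed
#' from the reduced design, never cached.
#'
#' @param design a [KineticDesign-class]
#' @param array_id array to remove
#' @export
dropArray <- function(design, array_id) {
  obs <- observations(design)
  if (!array_id %in% obs$array_id) stop("no such array: ", array_id)
  cmp <- comparisons(design)
  cmp$array_1[cmp$array_1 %in% array_id] <- NA_integer_
  cmp$array_2[cmp$array_2 %in% array_id] <- NA_integer_
  cmp <- cmp[!(is.na(cmp$array_1) & is.na(cmp$array_2)), , drop = FALSE]
  new("KineticDesign",
      observations = obs[obs$array_id != array_id, , drop = FALSE],
      comparisons = cmp)
}

#' Is the comparison graph over cells connected?
#'
#' Cells are nodes; each comparison is an edge. A connected graph means
#' every cell contrast is (indirectly) estimable.
#'
#' @param design a [KineticDesign-class]
#' @return logical
#' @export
isConnectedDesign <- function(design) {
  cmp <- comparisons(design)
  cells <- designCells(design)
  key <- function(t, p) paste(t, p, sep = "|")
  nodes <- key(cells$time_h, cells$treatment)
  adj <- cbind(key(cmp$time_a, cmp$treatment_a), key(cmp$time_b, cmp$treatment_b))
  seen <- nodes[1L]
  repeat {
    hit <- adj[, 1L] %in% seen | adj[, 2L] %in% seen
    grow <- unique(c(adj[hit, 1L], adj[hit, 2L]))
    if (all(grow %in% seen)) break
    seen <- union(seen, grow)
  }
  all(nodes %in% seen)
}
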