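## Plain-CSV import/export of thermogram cohorts.
##
## Two dialects: "long" with columns sample_id,temperature_C,cp and "wide"
## with a temperature_C column plus one column per sample. Labels and
## metadata travel in a sidecar CSV (sample_id,label,confirmed,<meta...>).
## Raw instrument exports vary by vendor; these dialects are the package's
## interchange convention.

.requireColumns <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
        stop(sprintf("%s: missing column(s) %s", what,
            paste(missing, collapse = ", ")), call. = FALSE)
}

.parseLabels <- function(labelsPath) {
    lab <- read.csv(labelsPath, stringsAsFactors = FALSE,
                    check.names = FALSE)
    .requireColumns(lab, c("sample_id", "label", "confirmed"), "labels file")
    if (!all(lab$label %in% c("negative", "positive", "", NA)))
        stop("labels file: label must be 'negative' or 'positive'",
             call. = FALSE)
    conf <- tolower(as.character(lab$confirmed)) %in% c("true", "1", "yes")
    metaCols <- setdiff(names(lab), c("sample_id", "label", "confirmed"))
    list(
        classLabel = setNames(as.character(lab$label),
                              lab$sample_id)[nzchar(lab$label) &
                                             !is.na(lab$label)],
        confirmed = setNames(conf, lab$sample_id),
        meta = lapply(setNames(seq_len(nrow(lab)), lab$sample_id),
            function(i) {
                m <- as.list(vapply(metaCols, function(cn)
                    as.character(lab[[cn]][i]), character(1)))
                m[vapply(m, function(v) !is.na(v) && nzchar(v), logical(1))]
            })
    )
}

#' Read a thermogram cohort from CSV
#'
#' @param path CSV of curves. Long layout: columns
#'   `sample_id,temperature_C,cp`. Wide layout: `temperature_C` plus one
#'   column per sample.
#' @param layout `"long"` or `"wide"`.
#' @param labelsPath optional sidecar CSV `sample_id,label,confirmed` with
#'   any further columns kept as per-sample string metadata.
#' @return A [ThermogramCohort-class]; rows are sorted by temperature within
#'   each sample and all cohort invariants are enforced.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' df <- data.frame(sample_id = rep(c("a", "b"), each = 3),
#'                  temperature_C = rep(c(40, 41, 42), 2),
#'                  cp = rnorm(6))
#' write.csv(df, tmp, row.names = FALSE)
#' cohort <- readCohort(tmp)
#' @export
readCohort <- function(path, layout = c("long", "wide"), labelsPath = NULL) {
    layout <- match.arg(layout)
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

    sideMeta <- NULL
    classLabel <- character(); confirmed <- logical()
    if (!is.null(labelsPath)) {
        side <- .parseLabels(labelsPath)
        classLabel <- side$classLabel
        confirmed <- side$confirmed
        sideMeta <- side$meta
    }

    makeTg <- function(id, tt, cc) {
        o <- order(tt)
        tt <- tt[o]; cc <- cc[o]
        if (anyDuplicated(tt))
            stop(sprintf(
                "duplicated temperature value(s) within sample '%s'", id),
                call. = FALSE)
        meta <- if (!is.null(sideMeta) && id %in% names(sideMeta))
            sideMeta[[id]] else list()
        Thermogram(id, tt, cc, meta = meta)
    }

    if (layout == "long") {
        .requireColumns(df, c("sample_id", "temperature_C", "cp"),
                        "long cohort file")
        ids <- unique(df$sample_id)
        tgs <- lapply(ids, function(id) {
            rows <- df$sample_id == id
            makeTg(id, df$temperature_C[rows], df$cp[rows])
        })
    } else {
        .requireColumns(df, "temperature_C", "wide cohort file")
        ids <- setdiff(names(df), "temperature_C")
        if (!length(ids))
            stop("wide cohort file: no sample columns", call. = FALSE)
        tgs <- lapply(ids, function(id)
            makeTg(id, df$temperature_C, df[[id]]))
    }

    # labels naming samples absent from the curves file fail cohort validity
    ThermogramCohort(tgs, classLabel = classLabel, confirmed = confirmed)
}

#' Write a thermogram cohort to CSV
#'
#' Inverse of [readCohort()]: `readCohort(writeCohort(x))` reproduces the
#' cohort up to float round-trip. The wide layout requires all samples to
#' share one temperature grid.
#'
#' @param cohort a [ThermogramCohort-class].
#' @param path output CSV path for the curves.
#' @param layout `"long"` or `"wide"`.
#' @param labelsPath optional path for the labels/metadata sidecar CSV.
#' @return `invisible(NULL)`.
#' @export
writeCohort <- function(cohort, path, layout = c("long", "wide"),
                        labelsPath = NULL) {
    stopifnot(is(cohort, "ThermogramCohort"))
    layout <- match.arg(layout)
    tgs <- cohort@thermograms

    if (layout == "long") {
        df <- if (length(tgs)) {
            do.call(rbind, lapply(tgs, function(tg)
                data.frame(sample_id = tg@sampleId,
                           temperature_C = tg@temperature, cp = tg@cp)))
        } else {
            data.frame(sample_id = character(), temperature_C = numeric(),
                       cp = numeric())
        }
    } else {
        if (length(tgs)) {
            tref <- tgs[[1L]]@temperature
            same <- vapply(tgs, function(tg)
                length(tg@temperature) == length(tref) &&
                    all(tg@temperature == tref), logical(1))
            if (!all(same))
                stop("wide layout requires a common temperature grid",
                     call. = FALSE)
            df <- data.frame(temperature_C = tref)
            for (tg in tgs) df[[tg@sampleId]] <- tg@cp
        } else {
            df <- data.frame(temperature_C = numeric())
        }
    }
    write.csv(df, path, row.names = FALSE, quote = FALSE)

    if (!is.null(labelsPath)) {
        ids <- sampleIds(cohort)
        lab <- classLabels(cohort)
        conf <- confirmedFlags(cohort)
        side <- data.frame(sample_id = ids,
            label = ifelse(is.na(lab), "", lab),
            confirmed = ifelse(is.na(conf), "false",
                               ifelse(conf, "true", "false")))
        metaKeys <- unique(unlist(lapply(tgs, function(tg) names(tg@meta))))
        for (k in metaKeys)
            side[[k]] <- vapply(tgs, function(tg) {
                v <- tg@meta[[k]]
                if (is.null(v)) "" else as.character(v)
            }, character(1))
        write.csv(side, labelsPath, row.names = FALSE, quote = FALSE)
    }
    invisible(NULL)
}
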