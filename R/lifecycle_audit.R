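#' @title Alert lifecycle and audit log
#' @description Every rule firing and every clinician reaction is
#'   registered in an append-only log — the raw material for later review
#'   of alert relevancy and override rates. Overriding an alert never
#'   suppresses future firings: alerts reappear with every subsequent
#'   prescription event (new, refill or revision) for as long as their
#'   trigger holds. Pregnancy alerts additionally expire nine months after
#'   detection or whenever a termination is recorded.
#' @name lifecycle_audit
NULL

#' Create an audit log
#'
#' An in-memory append-only sequence of entries, optionally mirrored to a
#' JSONL file (one JSON object per line, ISO-8601 timestamps) so the log
#' is greppable and diff-friendly. All log operations return a new log
#' value; prior entries are never mutated or deleted.
#'
#' @param path optional JSONL file to append every entry to.
#' @return object of class `dli_audit_log`.
#' @export
audit_log <- function(path = NULL) {
  structure(list(entries = list(), path = path), class = "dli_audit_log")
}

append_entry <- function(log, entry) {
  log$entries[[length(log$entries) + 1L]] <- entry
  if (!is.null(log$path)) {
    con <- file(log$path, open = "a")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null"), con)
  }
  log
}

#' Register rule firings in the audit log
#'
#' Each fired alert becomes one immutable entry with `reaction = "none"`
#' until a reaction is recorded via [record_reaction()].
#'
#' @param log a [audit_log()].
#' @param alerts a `dli_alerts` list from [evaluate()].
#' @param at firing timestamp (date).
#' @param actor identifier of the evaluating system/user.
#' @return the updated log.
#' @export
log_firing <- function(log, alerts, at, actor = "engine") {
  at <- as_date(at)
  for (a in alerts) {
    entry <- list(
      entry_id = sprintf("e%04d", length(log$entries) + 1L),
      event = "fired", alert_id = a$alert_id, rule_id = a$rule_id,
      patient_id = a$patient_id, severity_level = a$severity_level,
      fired_at = format(at, "%Y-%m-%d"), reaction = "none",
      reacted_at = NULL, actor = actor)
    log <- append_entry(log, entry)
  }
  log
}

.reactions <- c("none", "override", "stop_medication", "revise_medication",
                "order_lab")

#' Record a clinician's reaction to a fired alert
#'
#' Appends a reaction entry; never mutates the firing entry. Level-1
#' (interruptive) alerts require a reaction before the prescription event
#' can be marked complete — see [can_complete()]; levels 2 and 3 complete
#' without one.
#'
#' @param log a [audit_log()] in which the alert was registered as fired.
#' @param alert the alert object (or its `alert_id` string).
#' @param reaction one of `"override"`, `"stop_medication"`,
#'   `"revise_medication"`, `"order_lab"`.
#' @param actor opaque identifier of the reacting clinician.
#' @param at reaction timestamp; must not precede the firing.
#' @return the updated log.
#' @export
record_reaction <- function(log, alert, reaction, actor, at) {
  reaction <- match.arg(reaction, setdiff(.reactions, "none"))
  at <- as_date(at)
  alert_id <- if (is.character(alert)) alert else alert$alert_id
  fired <- Filter(function(e) e$event == "fired" && e$alert_id == alert_id,
                  log$entries)
  if (!length(fired))
    stop("no fired alert with id '", alert_id, "' in the audit log", call. = FALSE)
  fired_at <- as_date(fired[[1]]$fired_at)
  if (at < fired_at)
    stop("reaction timestamp ", format(at), " precedes firing ", format(fired_at),
         call. = FALSE)
  entry <- list(
    entry_id = sprintf("e%04d", length(log$entries) + 1L),
    event = "reaction", alert_id = alert_id, rule_id = fired[[1]]$rule_id,
    patient_id = fired[[1]]$patient_id,
    severity_level = fired[[1]]$severity_level,
    fired_at = fired[[1]]$fired_at, reaction = reaction,
    reacted_at = format(at, "%Y-%m-%d"), actor = actor)
  append_entry(log, entry)
}

#' Can a prescription event be marked complete?
#'
#' Only level-1 alerts oblige a reaction; the event is complete once every
#' fired level-1 alert for the patient has at least one reaction entry.
#'
#' @param log a [audit_log()].
#' @param patient_id the patient whose event is closing.
#' @return logical.
#' @export
can_complete <- function(log, patient_id) {
  fired1 <- Filter(function(e) e$event == "fired" && e$patient_id == patient_id &&
                     e$severity_level == 1L, log$entries)
  reacted <- vapply(Filter(function(e) e$event == "reaction", log$entries),
                    `[[`, "", "alert_id")
  all(vapply(fired1, `[[`, "", "alert_id") %in% reacted)
}

#' Should an alert reappear at a new prescription event?
#'
#' True whenever the rule's trigger still holds at the new event's
#' evaluation — regardless of any prior override recorded in the log.
#' Refills and revisions re-evaluate exactly like new prescriptions.
#'
#' @param log the audit log (consulted for nothing but kept in the
#'   signature to make the anti-suppression contract explicit).
#' @param rule_id the rule whose reappearance is queried.
#' @param patient,labs current patient state.
#' @param new_event the triggering [prescription()] event.
#' @param kb the knowledge base.
#' @param as_of evaluation date (defaults to the event's start date).
#' @param config an [engine_config()].
#' @return logical.
#' @export
should_reappear <- function(log, rule_id, patient, labs, new_event, kb,
                            as_of = new_event$start_date,
                            config = engine_config()) {
  alerts <- evaluate(patient, labs, list(new_event), kb, as_of, config)
  rule_id %in% vapply(alerts, `[[`, "", "rule_id")
}

#' Is a pregnancy episode still driving alerts?
#'
#' Pregnancy alerts expire after nine calendar months (boundary exclusive:
#' at the instant the ninth month completes) or whenever a termination is
#' recorded, whichever comes first.
#'
#' @param preg a [pregnancy_record()].
#' @param as_of evaluation date.
#' @param expiry_months months until expiry (default 9).
#' @return logical.
#' @examples
#' pr <- pregnancy_record("2020-01-10")
#' pregnancy_alert_active(pr, "2020-09-09")  # TRUE (8 months in)
#' pregnancy_alert_active(pr, "2020-11-10")  # FALSE (10 months in)
#' @export
pregnancy_alert_active <- function(preg, as_of, expiry_months = 9) {
  as_of <- as_date(as_of)
  expiry <- add_months(preg$detected_date, expiry_months)
  if (as_of >= expiry) return(FALSE)
  if (!is.null(preg$termination_date) && as_of >= preg$termination_date)
    return(FALSE)
  TRUE
}

#' Read an audit log back from its JSONL file
#'
#' @param path JSONL file written via [audit_log()]'s `path` mirror.
#' @return a `dli_audit_log` with the same entries.
#' @export
read_audit_log <- function(path) {
  lines <- readLines(path)
  log <- audit_log()
  log$entries <- lapply(lines, function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE))
  log
}

#' Per-rule firing and reaction summary
#'
#' Supports review of alert relevancy: firings, reaction mix, and the
#' override rate (overrides / reactions) per rule.
#'
#' @param log a `dli_audit_log`.
#' @return data.frame with one row per rule: `rule_id`, `firings`,
#'   `reactions`, `overrides`, `stops`, `revisions`, `lab_orders`,
#'   `override_rate`.
#' @export
audit_summary <- function(log) {
  fired <- Filter(function(e) e$event == "fired", log$entries)
  reacts <- Filter(function(e) e$event == "reaction", log$entries)
  ids <- sort(unique(vapply(fired, `[[`, "", "rule_id")))
  rows <- lapply(ids, function(rid) {
    f <- sum(vapply(fired, function(e) e$rule_id == rid, logical(1)))
    rr <- Filter(function(e) e$rule_id == rid, reacts)
    mix <- table(factor(vapply(rr, `[[`, "", "reaction"),
                        levels = setdiff(.reactions, "none")))
    data.frame(rule_id = rid, firings = f, reactions = length(rr),
               overrides = as.integer(mix[["override"]]),
               stops = as.integer(mix[["stop_medication"]]),
               revisions = as.integer(mix[["revise_medication"]]),
               lab_orders = as.integer(mix[["order_lab"]]),
               override_rate = if (length(rr)) as.integer(mix[["override"]]) / length(rr)
                               else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(rule_id = character(), firings = integer(),
                      reactions = integer(), overrides = integer(),
                      stops = integer(), revisions = integer(),
                      lab_orders = integer(), override_rate = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.dli_audit_log <- function(x, ...) {
  cat(sprintf("<audit log: %d entries%s>\n", length(x$entries),
              if (!is.null(x$path)) paste0(" -> ", x$path) else ""))
  invisible(x)
}
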