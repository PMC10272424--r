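# Typed error/warning helpers. Every user-facing failure mode carries a
# condition class of the form "hemomap_<what>" so callers (and tests) can
# discriminate failures without string matching.

hm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hemomap_error"), call = call))
}

hm_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "hemomap_warning")))
}
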