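# Shared objects for the test suite. Centering for the non-AMI equations is
# synthetic (the published constants are available only for the AMI
# equations), which leaves hazard ratios and shape properties untouched.

ndr_lib <- ndr_equations()
ndr_lib_centered <- synthetic_centering(ndr_lib)
wx_profile <- example_profile()

# worked-example first/second AMI risks computed from the printed formula by
# independent arithmetic (frozen oracle values)
WX_LP_FIRST <- -7.567638
WX_LP_SECOND <- -2.341386
WX_CUMHAZ_FIRST <- exp(WX_LP_FIRST) * (15^2.0537 - 10^2.0537)

# profile sitting exactly at the first-AMI centering constants, indicators 0
centered_ami_profile <- function() {
  data.frame(female = 0, age_at_diagnosis = 56.02, hba1c = 7.27,
             systolic_bp = 140.92, ldl = 2.77, tc_hdl = 3.89,
             macroalbuminuria = 0, microalbuminuria = 0, smoker = 0,
             ami_history = 0, hf_post = 0, duration_first_event = 10)
}

# small synthetic single-equation libraries for microsim oracles
flat_hazard_equation <- function(log_rate, shape = 1) {
  risk_equation("ami", "first", constant = log_rate, shape = shape,
                strict = FALSE)
}

# brute-force all-pairs concordance oracle (independent of harrell_c)
brute_force_c <- function(scores, times, events, entry = rep(0, length(scores))) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # usable iff the shorter follow-up ends in an event while the other
      # subject is at risk
      if (times[i] == times[j]) next
      s <- if (times[i] < times[j]) i else j  # shorter
      l <- if (times[i] < times[j]) j else i
      if (events[s] != 1) next
      if (entry[l] >= times[s]) next
      den <- den + 1
      if (scores[s] > scores[l]) num <- num + 1
      else if (scores[s] == scores[l]) num <- num + 0.5
    }
  }
  num / den
}
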