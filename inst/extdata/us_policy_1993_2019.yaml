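# US tobacco-control policy levels, 1993-2019.
# Verbal trajectories ("gradually increased to ...") are encoded as
# keyframes; linear interpolation between keyframes for coverages and
# prices, step interpolation for discrete coverage stages and the
# youth-access enforcement level.
name: us_default
years: {start: 1993, end: 2019}

# inflation-adjusted retail price per pack (USD)
price:
  interp: linear
  values: {1993: 1.75, 2002: 3.60, 2012: 5.60, 2019: 6.60}

smoke_free_air:
  enforcement: 8          # 0-10 scale, constant
  venues:
    worksite:             # ban strength mix: high = total ban,
                          # mid = ventilated areas allowed, low = common
                          # areas allowed
      high: {interp: linear, values: {1993: 0.015, 2002: 0.015, 2019: 0.761}}
      mid:  {interp: linear, values: {1993: 0.07, 2002: 0.07, 2019: 0.104}}
      low:  {interp: linear, values: {1993: 0.37, 2002: 0.37, 2019: 0.135}}
    restaurant:
      interp: linear
      values: {1993: 0.005, 2002: 0.005, 2014: 0.77, 2019: 0.778}
    bar:
      interp: linear
      values: {1993: 0.0, 2001: 0.0, 2014: 0.65, 2019: 0.664}
    other:
      interp: linear
      values: {1993: 0.5, 1998: 0.5, 2012: 0.948, 2019: 0.95}

media:
  weights:                # level mixture, sums to 1 each year
    minimal:
      interp: linear
      values: {1993: 0.9, 1994: 0.9, 2003: 0.0, 2010: 0.0, 2011: 0.5,
               2017: 0.5, 2018: 0.25, 2019: 0.25}
    moderate:
      interp: linear
      values: {1993: 0.1, 1994: 0.1, 2003: 1.0, 2010: 1.0, 2011: 0.5,
               2017: 0.5, 2018: 0.75, 2019: 0.75}
    high:
      interp: linear
      values: {1993: 0.0, 2019: 0.0}

marketing:
  enforcement: 9
  weights:
    minimal:       {interp: step, values: {1993: 1.0, 2010: 0.75}}
    moderate:      {interp: step, values: {1993: 0.0, 2010: 0.25}}
    comprehensive: {interp: step, values: {1993: 0.0}}

cessation_treatment:
  components:             # population coverage of each component
    availability:       {interp: step, values: {1993: 1.0}}
    financial_coverage: {interp: step, values: {1993: 0.0, 1997: 0.30,
                                                2002: 0.40, 2007: 0.50,
                                                2014: 0.75}}
    quitline:           {interp: linear, values: {1993: 0.0, 2002: 0.0,
                                                  2003: 0.50, 2007: 0.90,
                                                  2019: 0.90}}
    brief_intervention: {interp: step, values: {1993: 0.50}}

youth_access:
  level:
    interp: step
    values: {1993: none, 1998: low, 2003: moderate}
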