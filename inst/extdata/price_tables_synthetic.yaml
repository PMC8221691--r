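# Illustrative synthetic price tables for the carecost package.
#
# These are NOT published tariffs.  They are plausible standard unit
# costs, constructed for demonstration, testing and simulation: a
# Dutch-style reference set and an Italian-style alternate set used by
# the price-swap sensitivity analysis.  Replace with real standard-cost
# tables for substantive work.
tables:
  dutch_reference:
    currency: EUR
    year: 2014
    unit_costs:
      hospital_night: 476.0
      er_visit: 259.0
      physician_visit: 33.0
      home_care_hour: 73.0
      therapist_hour: 40.0
      supportive_unit: 18.0
      other_healthcare_unit: 35.0
    informal_care_wage: 14.5
    facility_per_diem:
      nursing_home: 167.0
      residential_care: 120.0
      rehabilitation: 350.0
    hospital_los:
      NL: 6.5
      IT: 7.8
      IS: 5.9
      FI: 7.3
      GE: 7.6
    recorded_days_country: BE
  italian_alternate:
    currency: EUR
    year: 2015
    unit_costs:
      hospital_night: 674.0
      er_visit: 242.0
      physician_visit: 21.0
      home_care_hour: 21.5
      therapist_hour: 24.0
      supportive_unit: 11.0
      other_healthcare_unit: 28.0
    informal_care_wage: 9.1
    facility_per_diem:
      nursing_home: 105.0
      residential_care: 86.0
      rehabilitation: 230.0
    hospital_los:
      NL: 6.5
      IT: 7.8
      IS: 5.9
      FI: 7.3
      GE: 7.6
    recorded_days_country: BE
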