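# Synthetic decadal atmospheric CO2 concentration pathways (ppm), 1850-2300.
# Approximation to the published RCP concentration pathways (RCP2.6, RCP4.5,
# RCP8.5 and their extensions), rounded to whole ppm and smoothed to decadal
# resolution; NOT the official tables. Shared historical segment to 2005.
# Interpolated to annual resolution by rcp_co2_pathway().
year,rcp26,rcp45,rcp85
1850,284.7,284.7,284.7
1860,286.8,286.8,286.8
1870,288.9,288.9,288.9
1880,291.3,291.3,291.3
1890,294.3,294.3,294.3
1900,296.7,296.7,296.7
1910,300.1,300.1,300.1
1920,303.4,303.4,303.4
1930,307.2,307.2,307.2
1940,310.4,310.4,310.4
1950,312.8,312.8,312.8
1960,316.6,316.6,316.6
1970,325.0,325.0,325.0
1980,338.4,338.4,338.4
1990,353.9,353.9,353.9
2000,368.9,368.9,368.9
2010,389.3,389.1,389.9
2020,412.1,411.1,415.8
2030,430.8,423.4,448.8
2040,440.2,444.0,489.4
2050,442.7,486.5,540.5
2060,441.7,508.9,610.6
2070,437.5,524.3,669.7
2080,431.6,531.1,758.2
2090,426.0,536.0,844.8
2100,420.9,538.4,935.9
2110,417.0,541.0,1030.0
2120,413.0,543.0,1130.0
2130,410.0,543.0,1230.0
2140,406.0,543.0,1330.0
2150,403.0,543.0,1430.0
2160,399.0,543.0,1520.0
2170,396.0,543.0,1600.0
2180,392.0,543.0,1680.0
2190,389.0,543.0,1740.0
2200,385.0,543.0,1800.0
2210,382.0,543.0,1840.0
2220,378.0,543.0,1880.0
2230,375.0,543.0,1910.0
2240,371.0,543.0,1935.0
2250,368.0,543.0,1955.0
2260,366.0,543.0,1962.0
2270,364.0,543.0,1962.0
2280,362.0,543.0,1962.0
2290,361.0,543.0,1962.0
2300,360.0,543.0,1962.0
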