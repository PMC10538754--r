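<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="C" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="D" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="E" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="F" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_E1" value="0" constant="true"/>
      <parameter id="ub_E1" value="1000" constant="true"/>
      <parameter id="lb_E2" value="0" constant="true"/>
      <parameter id="ub_E2" value="1000" constant="true"/>
      <parameter id="lb_E3" value="0" constant="true"/>
      <parameter id="ub_E3" value="1000" constant="true"/>
      <parameter id="lb_E4" value="0" constant="true"/>
      <parameter id="ub_E4" value="1000" constant="true"/>
      <parameter id="lb_R1" value="0" constant="true"/>
      <parameter id="ub_R1" value="1000" constant="true"/>
      <parameter id="lb_R2" value="0" constant="true"/>
      <parameter id="ub_R2" value="1000" constant="true"/>
      <parameter id="lb_R3" value="0" constant="true"/>
      <parameter id="ub_R3" value="1000" constant="true"/>
      <parameter id="lb_R4" value="0" constant="true"/>
      <parameter id="ub_R4" value="1000" constant="true"/>
      <parameter id="lb_R5" value="0" constant="true"/>
      <parameter id="ub_R5" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="E1" reversible="false" fast="false" fbc:lowerFluxBound="lb_E1" fbc:upperFluxBound="ub_E1">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Exchange</p>
          </body>
        </notes>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="E2" reversible="false" fast="false" fbc:lowerFluxBound="lb_E2" fbc:upperFluxBound="ub_E2">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Exchange</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="E3" reversible="false" fast="false" fbc:lowerFluxBound="lb_E3" fbc:upperFluxBound="ub_E3">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Exchange</p>
          </body>
        </notes>
        <listOfProducts>
          <speciesReference species="E" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="E4" reversible="false" fast="false" fbc:lowerFluxBound="lb_E4" fbc:upperFluxBound="ub_E4">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Exchange</p>
          </body>
        </notes>
        <listOfProducts>
          <speciesReference species="F" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb_R1" fbc:upperFluxBound="ub_R1">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Core conversion</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="lb_R2" fbc:upperFluxBound="ub_R2">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Core conversion</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="lb_R3" fbc:upperFluxBound="ub_R3">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Core conversion</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R4" reversible="false" fast="false" fbc:lowerFluxBound="lb_R4" fbc:upperFluxBound="ub_R4">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Core conversion</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="E" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R5" reversible="false" fast="false" fbc:lowerFluxBound="lb_R5" fbc:upperFluxBound="ub_R5">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: Core conversion</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="F" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
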